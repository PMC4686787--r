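<?xml version="1.0" encoding="UTF-8"?>
<!-- Packaged example protocol. Activity/attribute names beyond those on public record, and all numbered condition/disease labels, are reconstructions: they exercise workflow structure and attribute types, not medical content. -->
<Package xmlns="http://www.wfmc.org/2008/XPDL2.2" Id="ald" Name="Adrenoleukodystrophy protocol">
  <PackageHeader>
    <XPDLVersion>2.2</XPDLVersion>
    <Vendor>fluxcase</Vendor>
  </PackageHeader>
  <RedefinableHeader>
    <Version>1.0</Version>
  </RedefinableHeader>
  <ExtendedAttributes>
    <ExtendedAttribute Name="FLUX_REGISTRY" Value="NAME=treatments;EXTENSIBLE=true;ENTRIES=Lorenzo's oil,Corticosteroid replacement,Dietary therapy,Stem cell transplantation"/>
    <ExtendedAttribute Name="FLUX_REGISTRY" Value="NAME=symptoms;EXTENSIBLE=true;ENTRIES=Fatigue,Leg Pain"/>
    <ExtendedAttribute Name="FLUX_SUGGEST" Value="ID=high_vlcfa;SOURCE=clinical_evolution;CONDITION=vlcfa_level &gt; 1.5;SUGGEST=mri_encephalon,adrenal_function_test"/>
    <ExtendedAttribute Name="FLUX_SUGGEST" Value="ID=adrenal_insufficiency;SOURCE=adrenal_function_test;CONDITION=cortisol_basal &lt; 5;SUGGEST=neurological_examination,mri_spinal_cord"/>
  </ExtendedAttributes>
  <WorkflowProcesses>
    <WorkflowProcess Id="ald_process" Name="Adrenoleukodystrophy protocol">
      <Activities>
        <Activity Id="diagnosis_information" Name="Diagnosis Information">
          <ExtendedAttributes>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=patient_initials;KIND=text;REQUIRED=true;EXAMPLE=J.S."/>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=birth_date;KIND=date;REQUIRED=true"/>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=place_of_birth;KIND=text;REQUIRED=false"/>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=previous_record_number;KIND=integer;REQUIRED=false;MIN=1"/>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=genotype;KIND=text;REQUIRED=false"/>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=first_symptom_date;KIND=date;REQUIRED=false"/>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=first_symptoms;KIND=text;REQUIRED=false"/>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=age_at_first_symptom;KIND=computed;REQUIRED=false;FORMULA=years_between(first_symptom_date, birth_date)"/>
          </ExtendedAttributes>
        </Activity>
        <Activity Id="treatment" Name="Treatment">
          <ExtendedAttributes>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=treatment;KIND=register;REQUIRED=true;REGISTRY=treatments;HINT=Pick a pre-built treatment or register a new one first"/>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=start_date;KIND=date;REQUIRED=false"/>
          </ExtendedAttributes>
        </Activity>
        <Activity Id="symptoms" Name="Symptoms">
          <ExtendedAttributes>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=symptom;KIND=register;REQUIRED=false;REGISTRY=symptoms"/>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=severity;KIND=choice;REQUIRED=false;CHOICES=mild,moderate,severe"/>
          </ExtendedAttributes>
        </Activity>
        <Activity Id="clinical_evolution" Name="Clinical Evolution">
          <ExtendedAttributes>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=visit_date;KIND=date;REQUIRED=true"/>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=vlcfa_level;KIND=real;REQUIRED=false;MIN=0;MAX=10;HINT=Very-long-chain fatty acid level (C26:0, ug/mL)"/>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=notes;KIND=text;REQUIRED=false"/>
          </ExtendedAttributes>
        </Activity>
        <Activity Id="mri_encephalon" Name="MRI Encephalon">
          <ExtendedAttributes>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=loes_score;KIND=real;REQUIRED=false;MIN=0;MAX=34"/>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=result;KIND=choice;REQUIRED=false;CHOICES=normal,abnormal"/>
          </ExtendedAttributes>
        </Activity>
        <Activity Id="adrenal_function_test" Name="Adrenal Function Test">
          <ExtendedAttributes>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=cortisol_basal;KIND=real;REQUIRED=false;MIN=0;MAX=100"/>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=acth;KIND=real;REQUIRED=false;MIN=0;MAX=2000"/>
          </ExtendedAttributes>
        </Activity>
        <Activity Id="neurological_examination" Name="Neurological Examination">
          <ExtendedAttributes>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=findings;KIND=text;REQUIRED=false"/>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=motor_deficit;KIND=choice;REQUIRED=false;CHOICES=yes,no"/>
          </ExtendedAttributes>
        </Activity>
        <Activity Id="mri_spinal_cord" Name="MRI Spinal Cord">
          <ExtendedAttributes>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=result;KIND=choice;REQUIRED=false;CHOICES=normal,abnormal"/>
          </ExtendedAttributes>
        </Activity>
        <Activity Id="other_information" Name="Other Information">
          <ExtendedAttributes>
            <ExtendedAttribute Name="FLUX_FIELD" Value="NAME=notes;KIND=text;REQUIRED=false"/>
          </ExtendedAttributes>
        </Activity>
      </Activities>
      <Transitions>
        <Transition Id="t1" From="diagnosis_information" To="treatment"/>
        <Transition Id="t2" From="treatment" To="symptoms"/>
        <Transition Id="t3" From="symptoms" To="clinical_evolution"/>
        <Transition Id="t4" From="clinical_evolution" To="mri_encephalon"/>
        <Transition Id="t5" From="clinical_evolution" To="adrenal_function_test"/>
        <Transition Id="t6" From="clinical_evolution" To="neurological_examination"/>
        <Transition Id="t7" From="clinical_evolution" To="mri_spinal_cord"/>
        <Transition Id="t8" From="mri_encephalon" To="other_information"/>
        <Transition Id="t9" From="adrenal_function_test" To="other_information"/>
        <Transition Id="t10" From="neurological_examination" To="other_information"/>
        <Transition Id="t11" From="mri_spinal_cord" To="other_information"/>
      </Transitions>
    </WorkflowProcess>
  </WorkflowProcesses>
</Package>
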