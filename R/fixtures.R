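#' Packaged disease-protocol workflows
#'
#' Three complete protocols ship with the package as `.xpdl` files under
#' `extdata`, demonstrating that a new disease is a new workflow file and
#' never a code change:
#'
#' * `nmo` — neuromyelitis optica: 16 activities from identification
#'   through diagnosis and follow-up, including a repeating Family History
#'   table and a computed age-at-onset.
#' * `pcm` — paracoccidioidomycosis: identification by SAME number, a First
#'   Consultation battery of 35 present/absent medical conditions and 29
#'   yes/no disease-history questions, organ-system exams, and a concluding
#'   activity for diagnostic hypothesis, exams and prescriptions.
#' * `ald` — adrenoleukodystrophy: 9 activities with extensible treatment
#'   and symptom registries and suggestion rules that propose follow-up
#'   assays from earlier results.
#'
#' Only some activity and attribute names of these protocols are public
#' record; the remainder (and all condition/disease labels, which use
#' numbered placeholders) are reconstructions that exercise structure and
#' types, not medical content — the files say so in a header comment.
#'
#' @param name Fixture name: `"nmo"`, `"pcm"` or `"ald"`; a leading `@` (the
#'   CLI shorthand) is accepted.
#' @return `flux_fixture()`: the file path. `fixture_catalog()`: a data
#'   frame with one row per fixture (`name`, `path`, `activities`, and for
#'   `pcm` the condition/disease battery sizes).
#' @export
flux_fixture <- function(name) {
  name <- sub("^@", "", name)
  path <- system.file("extdata", paste0(name, ".xpdl"), package = "fluxcase")
  if (!nzchar(path)) {
    stop_flux("flux_unknown_fixture",
              sprintf("no packaged fixture named '%s' (have: nmo, pcm, ald)",
                      name))
  }
  path
}

#' @rdname flux_fixture
#' @export
fixture_catalog <- function() {
  names <- c("nmo", "pcm", "ald")
  rows <- lapply(names, function(nm) {
    path <- flux_fixture(nm)
    wf <- parse_workflow(path)
    cond <- dise <- NA_integer_
    if (nm == "pcm") {
      attrs <- wf$activities[["first_consultation"]]$attributes
      cond <- sum(grepl("^condition_[0-9]+$", names(attrs)))
      dise <- sum(grepl("^disease_[0-9]+$", names(attrs)))
    }
    data.frame(name = nm, path = path, activities = length(wf$activities),
               condition_attributes = cond, disease_attributes = dise,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

choice_yn <- function(name, ...) {
  attribute_def(name, "choice", choices = c("yes", "no"), ...)
}

# The 16-activity neuromyelitis optica protocol. Identification and Family
# History are documented protocol activities; the rest reconstruct the
# clinical pathway (symptoms, imaging, CSF, serology, diagnosis, treatment).
fixture_workflow_nmo <- function() {
  A <- activity_def
  at <- attribute_def
  acts <- list(
    A("identification", "Identification", list(
      at("name", "text", required = TRUE, hint = "Full patient name"),
      at("birth_date", "date", required = TRUE, example = "1980-06-01"),
      at("age", "integer", min = 0, max = 120),
      at("sex", "choice", choices = c("female", "male")),
      at("education", "choice",
         choices = c("none", "primary", "secondary", "higher")),
      at("city", "text"), at("state", "text"), at("country", "text"),
      at("attending_physician", "register", registry = "doctors"),
      at("first_evaluation_date", "date", required = TRUE,
         hint = "Date of first evaluation (later dates are compared to it)")
    )),
    A("clinical_history", "Clinical History", list(
      at("summary", "text", required = TRUE),
      at("comorbidities", "text")
    )),
    A("family_history", "Family History", list(
      at("relatives", "table", columns = c(
        relative = "text", condition = "text", onset_year = "integer"),
        hint = "One row per family member")
    )),
    A("first_symptoms", "First Symptoms", list(
      at("first_symptom_date", "date", required = TRUE),
      at("symptom_description", "text"),
      at("age_at_onset", "computed",
         formula = "years_between(first_symptom_date, birth_date)")
    )),
    A("optic_neuritis", "Optic Neuritis Assessment", list(
      at("affected_eye", "choice", choices = c("left", "right", "both")),
      at("visual_acuity", "real", min = 0, max = 2)
    )),
    A("myelitis", "Myelitis Assessment", list(
      at("spinal_level", "text"),
      at("extension_segments", "integer", min = 0, max = 30)
    )),
    A("neurological_examination", "Neurological Examination", list(
      at("edss_score", "real", min = 0, max = 10),
      at("findings", "text")
    )),
    A("mri_brain", "MRI Brain", list(
      at("result", "choice", choices = c("normal", "abnormal")),
      at("lesion_count", "integer", min = 0, max = 99)
    )),
    A("mri_spinal_cord", "MRI Spinal Cord", list(
      at("result", "choice", choices = c("normal", "abnormal")),
      at("longitudinally_extensive", "choice", choices = c("yes", "no"))
    )),
    A("evoked_potentials", "Visual Evoked Potentials", list(
      at("latency_ms", "real", min = 50, max = 300)
    )),
    A("csf_analysis", "CSF Analysis", list(
      at("cell_count", "integer", min = 0, max = 10000),
      at("oligoclonal_bands", "choice", choices = c("present", "absent"))
    )),
    A("aqp4_serology", "AQP4-IgG Serology", list(
      at("aqp4_igg", "choice",
         choices = c("positive", "negative", "indeterminate")),
      at("titer", "real", min = 0, max = 100000)
    )),
    A("differential_diagnosis", "Differential Diagnosis", list(
      choice_yn("ms_excluded"),
      at("notes", "text")
    )),
    A("diagnosis", "Diagnosis", list(
      choice_yn("nmo_confirmed", required = TRUE),
      at("diagnosis_date", "date")
    )),
    A("treatment", "Treatment Plan", list(
      at("medication", "text"),
      at("dose", "text")
    )),
    A("follow_up", "Follow Up", list(
      at("next_visit_date", "date"),
      at("status", "text")
    ))
  )
  tr <- list(
    c("identification", "clinical_history"),
    c("clinical_history", "family_history"),
    c("family_history", "first_symptoms"),
    c("first_symptoms", "optic_neuritis"),
    c("first_symptoms", "myelitis"),
    c("optic_neuritis", "neurological_examination"),
    c("myelitis", "neurological_examination"),
    c("neurological_examination", "mri_brain"),
    c("mri_brain", "mri_spinal_cord"),
    c("mri_spinal_cord", "evoked_potentials"),
    c("evoked_potentials", "csf_analysis"),
    c("csf_analysis", "aqp4_serology"),
    c("aqp4_serology", "differential_diagnosis"),
    c("differential_diagnosis", "diagnosis"),
    c("diagnosis", "treatment"),
    c("treatment", "follow_up")
  )
  workflow_def("nmo", "Neuromyelitis Optica protocol", acts, tr,
    registries = list(
      registry_def("doctors",
                   c("Dr. A. Souza", "Dr. B. Oliveira", "Dr. C. Santos"),
                   extensible = FALSE)
    ))
}

# The paracoccidioidomycosis protocol: identification by SAME number, the
# First Consultation battery (35 condition + 29 disease-history questions,
# placeholder labels), organ-system exams, and the concluding activity.
fixture_workflow_pcm <- function() {
  A <- activity_def
  at <- attribute_def
  conditions <- lapply(sprintf("condition_%02d", 1:35), function(nm) {
    attribute_def(nm, "choice", choices = c("present", "absent"))
  })
  diseases <- lapply(sprintf("disease_%02d", 1:29), choice_yn)
  acts <- list(
    A("identification", "Identification", list(
      at("same", "integer", required = TRUE, min = 1,
         hint = "SAME: the hospital's unique medical-history number"),
      at("protocol", "text"),
      at("name", "text", required = TRUE),
      at("birth_date", "date"),
      at("occupation", "text", example = "farm worker")
    )),
    A("first_consultation", "First Consultation", c(
      list(at("major_complaints", "text", required = TRUE)),
      conditions,
      list(at("other_conditions", "text",
              hint = "Conditions not covered by the battery above")),
      diseases,
      list(at("other_diseases", "text",
              hint = "Present or previous diseases not covered above"))
    )),
    A("respiratory_exam", "Respiratory System Exam", list(
      choice_yn("dyspnea"),
      at("auscultation", "text"),
      at("xray_result", "choice", choices = c("normal", "altered"))
    )),
    A("cardiovascular_exam", "Cardiovascular System Exam", list(
      at("heart_rate", "integer", min = 20, max = 250),
      at("blood_pressure", "text", example = "120/80"),
      at("alterations", "text")
    )),
    A("digestive_exam", "Digestive System Exam", list(
      choice_yn("hepatomegaly"),
      choice_yn("splenomegaly"),
      at("alterations", "text")
    )),
    A("conclusion", "Diagnostic Hypothesis, Exams and Prescriptions", list(
      at("diagnostic_hypothesis", "text", required = TRUE),
      at("exams_requested", "text"),
      at("prescriptions", "text")
    ))
  )
  tr <- list(
    c("identification", "first_consultation"),
    c("first_consultation", "respiratory_exam"),
    c("first_consultation", "cardiovascular_exam"),
    c("first_consultation", "digestive_exam"),
    c("respiratory_exam", "conclusion"),
    c("cardiovascular_exam", "conclusion"),
    c("digestive_exam", "conclusion")
  )
  workflow_def("pcm", "Paracoccidioidomycosis protocol", acts, tr)
}

# The 9-activity adrenoleukodystrophy protocol, with extensible treatment
# and symptom registries and two suggestion rules.
fixture_workflow_ald <- function() {
  A <- activity_def
  at <- attribute_def
  acts <- list(
    A("diagnosis_information", "Diagnosis Information", list(
      at("patient_initials", "text", required = TRUE, example = "J.S."),
      at("birth_date", "date", required = TRUE),
      at("place_of_birth", "text"),
      at("previous_record_number", "integer", min = 1),
      at("genotype", "text"),
      at("first_symptom_date", "date"),
      at("first_symptoms", "text"),
      at("age_at_first_symptom", "computed",
         formula = "years_between(first_symptom_date, birth_date)")
    )),
    A("treatment", "Treatment", list(
      at("treatment", "register", registry = "treatments", required = TRUE,
         hint = "Pick a pre-built treatment or register a new one first"),
      at("start_date", "date")
    )),
    A("symptoms", "Symptoms", list(
      at("symptom", "register", registry = "symptoms"),
      at("severity", "choice", choices = c("mild", "moderate", "severe"))
    )),
    A("clinical_evolution", "Clinical Evolution", list(
      at("visit_date", "date", required = TRUE),
      at("vlcfa_level", "real", min = 0, max = 10,
         hint = "Very-long-chain fatty acid level (C26:0, ug/mL)"),
      at("notes", "text")
    )),
    A("mri_encephalon", "MRI Encephalon", list(
      at("loes_score", "real", min = 0, max = 34),
      at("result", "choice", choices = c("normal", "abnormal"))
    )),
    A("adrenal_function_test", "Adrenal Function Test", list(
      at("cortisol_basal", "real", min = 0, max = 100),
      at("acth", "real", min = 0, max = 2000)
    )),
    A("neurological_examination", "Neurological Examination", list(
      at("findings", "text"),
      choice_yn("motor_deficit")
    )),
    A("mri_spinal_cord", "MRI Spinal Cord", list(
      at("result", "choice", choices = c("normal", "abnormal"))
    )),
    A("other_information", "Other Information", list(
      at("notes", "text")
    ))
  )
  tr <- list(
    c("diagnosis_information", "treatment"),
    c("treatment", "symptoms"),
    c("symptoms", "clinical_evolution"),
    c("clinical_evolution", "mri_encephalon"),
    c("clinical_evolution", "adrenal_function_test"),
    c("clinical_evolution", "neurological_examination"),
    c("clinical_evolution", "mri_spinal_cord"),
    c("mri_encephalon", "other_information"),
    c("adrenal_function_test", "other_information"),
    c("neurological_examination", "other_information"),
    c("mri_spinal_cord", "other_information")
  )
  workflow_def("ald", "Adrenoleukodystrophy protocol", acts, tr,
    registries = list(
      registry_def("treatments",
                   c("Lorenzo's oil", "Corticosteroid replacement",
                     "Dietary therapy", "Stem cell transplantation"),
                   extensible = TRUE),
      registry_def("symptoms", c("Fatigue", "Leg Pain"), extensible = TRUE)
    ),
    suggestion_rules = list(
      suggestion_rule("high_vlcfa", "clinical_evolution",
                      "vlcfa_level > 1.5",
                      c("mri_encephalon", "adrenal_function_test")),
      suggestion_rule("adrenal_insufficiency", "adrenal_function_test",
                      "cortisol_basal < 5",
                      c("neurological_examination", "mri_spinal_cord"))
    ))
}

fixture_builders <- function() {
  list(nmo = fixture_workflow_nmo,
       pcm = fixture_workflow_pcm,
       ald = fixture_workflow_ald)
}

# Regenerates the packaged fixture files (used at development time; the
# shipped .xpdl files are the artifact of record).
write_fixture_files <- function(dir) {
  header <- paste0(
    "<!-- Packaged example protocol. Activity/attribute names beyond those ",
    "on public record, and all numbered condition/disease labels, are ",
    "reconstructions: they exercise workflow structure and attribute types, ",
    "not medical content. -->")
  for (nm in names(fixture_builders())) {
    wf <- fixture_builders()[[nm]]()
    xml <- serialize_workflow(wf)
    xml <- sub("\\?>", paste0("?>\n", header), xml)
    writeLines(xml, file.path(dir, paste0(nm, ".xpdl")), useBytes = TRUE)
  }
  invisible(dir)
}
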