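#' System organ classes defining a cardiovascular adverse event
#'
#' A preferred term (PT) counts as cardiovascular when its system organ
#' class is one of these.
#' @export
cardiovascular_socs <- c("Cardiac disorders", "Vascular disorders")

#' The preferred term used to flag cytokine release syndrome
#' @export
crs_pt <- "Cytokine release syndrome"

#' Human-readable labels for ATC level-1 classes
#'
#' Anatomical main groups of the WHO ATC classification, plus the pooled
#' `other` group for concomitant drugs absent from the supplied mapping.
#' @export
atc1_labels <- c(
  A = "Digestive and metabolic system drugs",
  B = "Blood and hematopoietic organs medication",
  C = "Cardiovascular system medications",
  D = "Dermatological medications",
  G = "Genitourinary system and sexual hormones",
  H = "Systemic corticosteroids, excluding sexual hormones and insulin",
  J = "Systemic anti-infective agents",
  L = "Antineoplastic and immunomodulating agents",
  M = "Musculoskeletal system medications",
  N = "Nervous system medication",
  P = "Antiparasitic, insecticidal, and anthelmintic drugs",
  R = "Respiratory system medications",
  S = "Sensory organ system medications",
  other = "Other miscellaneous drugs"
)

#' Read a preferred-term to system-organ-class mapping
#'
#' A user-supplied surrogate for the licensed MedDRA dictionary: a TSV with
#' columns `pt` and `soc`.  The mapping must be a function (one SOC per PT);
#' duplicated PTs keep the first entry with a warning.
#'
#' @param file TSV path.
#' @return Tibble with columns `pt`, `soc`.
#' @export
read_pt_map <- function(file) {
  df <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  names(df) <- tolower(names(df))
  if (!all(c("pt", "soc") %in% names(df))) {
    stop("PT map must have columns pt, soc", call. = FALSE)
  }
  dup <- duplicated(tolower(trimws(df$pt)))
  if (any(dup)) {
    warning("PT map: dropped ", sum(dup), " duplicated PT row(s)",
            call. = FALSE)
  }
  as_tibble(df[!dup, c("pt", "soc")])
}

#' Read a drug-name to ATC level-1 class mapping
#'
#' TSV with columns `drugname` and `atc1` (a single letter A-V).  Matching
#' downstream is case-insensitive on the trimmed drug name.
#'
#' @param file TSV path.
#' @return Tibble with columns `drugname`, `atc1`.
#' @export
read_atc_map <- function(file) {
  df <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  names(df) <- tolower(names(df))
  if (!all(c("drugname", "atc1") %in% names(df))) {
    stop("ATC map must have columns drugname, atc1", call. = FALSE)
  }
  bad <- !grepl("^[A-V]$", df$atc1)
  if (any(bad)) {
    warning("ATC map: dropped ", sum(bad), " row(s) with invalid atc1 code",
            call. = FALSE)
  }
  as_tibble(df[!bad, c("drugname", "atc1")])
}

#' Built-in PT to SOC mapping
#'
#' A compact MedDRA-style surrogate covering the cardiovascular preferred
#' terms discussed in the pediatric CAR-T safety literature plus common
#' non-cardiovascular background terms.  Real analyses should supply their
#' own dictionary export via [read_pt_map()].
#'
#' @return Tibble with columns `pt`, `soc`.
#' @export
default_pt_map <- function() {
  tibble(
    pt = c(
      "Hypotension", "Hypertension", "Shock", "Capillary leak syndrome",
      "Tachycardia", "Sinus tachycardia", "Cardiac arrest",
      "Cardio-respiratory arrest", "Heart failure", "Pericardial effusion",
      "Mitral valve disease", "Mitral valve incompetence", "Bradycardia",
      "Cardiomyopathy", "Arrhythmia",
      "Cytokine release syndrome", "Pyrexia", "Febrile neutropenia",
      "Neutropenia", "Headache", "Seizure", "Vomiting", "Diarrhoea",
      "Acute kidney injury", "Hypoxia", "Fatigue", "Sepsis",
      "Neurotoxicity", "Encephalopathy", "Rash"
    ),
    soc = c(
      "Vascular disorders", "Vascular disorders", "Vascular disorders",
      "Vascular disorders",
      "Cardiac disorders", "Cardiac disorders", "Cardiac disorders",
      "Cardiac disorders", "Cardiac disorders", "Cardiac disorders",
      "Cardiac disorders", "Cardiac disorders", "Cardiac disorders",
      "Cardiac disorders", "Cardiac disorders",
      "Immune system disorders",
      "General disorders and administration site conditions",
      "Blood and lymphatic system disorders",
      "Blood and lymphatic system disorders",
      "Nervous system disorders", "Nervous system disorders",
      "Gastrointestinal disorders", "Gastrointestinal disorders",
      "Renal and urinary disorders",
      "Respiratory, thoracic and mediastinal disorders",
      "General disorders and administration site conditions",
      "Infections and infestations",
      "Nervous system disorders", "Nervous system disorders",
      "Skin and subcutaneous tissue disorders"
    )
  )
}

#' Built-in drug-name to ATC level-1 mapping
#'
#' Representative concomitant medications per anatomical main group, enough
#' to exercise the co-medication covariates; real analyses should supply a
#' fuller table via [read_atc_map()].
#'
#' @return Tibble with columns `drugname`, `atc1`.
#' @export
default_atc_map <- function() {
  tibble(
    drugname = c(
      "OMEPRAZOLE", "ONDANSETRON",            # A
      "HEPARIN", "FILGRASTIM",                # B
      "AMLODIPINE", "METOPROLOL", "NOREPINEPHRINE", # C
      "MUPIROCIN", "HYDROCORTISONE TOPICAL",  # D
      "OXYTOCIN", "ESTRADIOL",                # G
      "DEXAMETHASONE", "METHYLPREDNISOLONE",  # H
      "VANCOMYCIN", "MEROPENEM", "ACYCLOVIR", # J
      "CYCLOPHOSPHAMIDE", "FLUDARABINE", "RITUXIMAB", "TOCILIZUMAB", # L
      "IBUPROFEN", "BACLOFEN",                # M
      "LEVETIRACETAM", "MORPHINE", "LORAZEPAM", # N
      "IVERMECTIN", "ALBENDAZOLE",            # P
      "SALBUTAMOL", "MONTELUKAST",            # R
      "TIMOLOL EYE DROPS",                    # S
      "CONTRAST MEDIA AGENT"                  # V
    ),
    atc1 = c("A", "A", "B", "B", "C", "C", "C", "D", "D", "G", "G",
             "H", "H", "J", "J", "J", "L", "L", "L", "L", "M", "M",
             "N", "N", "N", "P", "P", "R", "R", "S", "V")
  )
}

#' Default synonym list for the target drug
#'
#' The tisagenlecleucel CAR T-cell product under its generic, brand and
#' development names.  Matching is case-insensitive substring on DRUGNAME
#' and PROD_AI.
#' @export
target_drug_synonyms <- c("TISAGENLECLEUCEL", "KYMRIAH", "CTL019", "CTL-019")
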