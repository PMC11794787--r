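#' Deterministic worked-example quarter with fixed cohort marginals
#'
#' A synthetic FAERS-style bundle whose pediatric target-drug cohort has
#' exactly the marginal counts used in the package's worked examples: 568
#' reports, 187 with a cardiovascular adverse event (57 fatal, 130
#' non-fatal), 381 without; 434 reports from the US (156 among CVAE); sex
#' counts 116/64/7 (M/F/missing) among CVAE and 219/149/13 among non-CVAE,
#' 39/16/2 among fatal CVAE; 310 physician reports; per-PT blocks of
#' hypotension (131; 118 with CRS, 38 fatal), tachycardia (68; all CRS, 31
#' fatal), shock (9; 6 fatal) and cardiac arrest (6; 1 fatal).  Onset-day
#' patterns give a median of 3 days (IQR 1-6) for CVAE and 7 days (IQR
#' 2-54) for non-CVAE reports.  A background comparator population is
#' appended from the generator under a fixed internal seed so the
#' disproportionality stage has non-cases to count against.
#'
#' Everything is synthetic and deterministic: two calls return identical
#' bundles.
#'
#' @param n_background Number of comparator (non-target) reports appended.
#' @return A `faers_bundle` (empty deletion list, no duplicate versions).
#' @export
fixture_quarter <- function(n_background = 3000L) {
  n <- 568L
  pid <- as.character(500000000L + seq_len(n))
  cid <- as.character(50000000L + seq_len(n))

  # order: 57 fatal CVAE, 130 non-fatal CVAE, 381 non-CVAE
  other_cty <- c("FR", "DE", "IT", "NL", "SE", "CH", "PL", "AT", "BE", "DK",
                 "NO")
  sex <- c(rep("M", 39), rep("F", 16), rep("", 2),
           rep("M", 77), rep("F", 48), rep("", 5),
           rep("M", 219), rep("F", 149), rep("", 13))
  country <- c(
    rep("US", 45), rep("CA", 4), rep("GB", 2), rep("AU", 2), "JP",
    other_cty[1:3],
    rep("US", 111), rep("ES", 5), "CA", rep("GB", 2), "AU", rep("JP", 2),
    other_cty[1:8],
    rep("US", 278), rep("JP", 19), rep("CA", 15), rep("ES", 12), rep("AU", 9),
    rep(other_cty[1:8], 6)
  )
  reporter <- c(
    rep("MD", 26), rep("PH", 19), rep("OT", 6), rep("CN", 5), "",
    rep("MD", 58), rep("PH", 45), rep("OT", 15), rep("CN", 11), "",
    rep("MD", 226), rep("PH", 73), rep("OT", 34), rep("CN", 46), rep("", 2)
  )
  age <- c(
    rep(2, 10), rep(4, 9), rep(5, 5), rep(7, 5), rep(10, 9), rep(14, 15),
    rep(16, 4),
    rep(5, 20), rep(8, 20), rep(9, 15), rep(11, 25), rep(13, 10), rep(14, 30),
    rep(16, 10),
    rep(3, 60), rep(6, 40), rep(8, 50), rep(11, 50), rep(13, 60), rep(14, 80),
    rep(17, 41)
  )
  stopifnot(length(sex) == n, length(country) == n, length(reporter) == n,
            length(age) == n)

  # exactly 40 fatal non-CVAE reports at deterministic positions
  fatal_ncv <- rep(FALSE, 381); fatal_ncv[seq(1, by = 9, length.out = 40)] <- TRUE
  is_fatal <- c(rep(TRUE, 57), rep(FALSE, 130), fatal_ncv)
  is_cvae <- c(rep(TRUE, 187), rep(FALSE, 381))

  # onset-day patterns (type-7 quantiles: 3 [1, 6] vs 7 [2, 54])
  days <- c(
    rep(1, 50), rep(2, 30), rep(3, 27), rep(4, 30), rep(6, 25), rep(10, 15),
    rep(30, 10),
    rep(2, 100), rep(5, 40), rep(7, 80), rep(12, 60), rep(54, 101)
  )
  stopifnot(length(days) == n)
  start <- as.Date("2023-01-10")
  event <- start + days
  fda <- event + 20

  # a slice of ages goes out in months to exercise unit normalization
  as_months <- seq_len(n) %in% seq(188, by = 12, length.out = 20)
  demo <- tibble(
    primaryid = pid, caseid = cid, fda_dt = format(fda, "%Y%m%d"),
    event_dt = format(event, "%Y%m%d"),
    age = ifelse(as_months, as.character(age * 12L), as.character(age)),
    age_cod = ifelse(as_months, "MON", "YR"),
    sex = sex, occr_country = country, occp_cod = reporter
  )

  # reactions ------------------------------------------------------------
  # fatal CVAE (1-57): 1-19 hypo+tachy, 20-38 hypo, 39-50 tachy,
  #                    51-56 shock, 57 arrest; CRS on all 57
  # non-fatal CVAE (58-187, local 1-130): 1-8 hypo+tachy, 9-93 hypo
  #   (CRS through local 80), 94-122 tachy, 123-125 shock, 126-130 arrest
  local <- function(i) 57L + i
  pt_of <- vector("list", n)
  crs <- rep(FALSE, n)
  for (i in 1:19)  pt_of[[i]] <- c("Hypotension", "Tachycardia")
  for (i in 20:38) pt_of[[i]] <- "Hypotension"
  for (i in 39:50) pt_of[[i]] <- "Tachycardia"
  for (i in 51:56) pt_of[[i]] <- "Shock"
  pt_of[[57]] <- "Cardiac arrest"
  crs[1:57] <- TRUE
  for (i in 1:8)     pt_of[[local(i)]] <- c("Hypotension", "Tachycardia")
  for (i in 9:93)    pt_of[[local(i)]] <- "Hypotension"
  for (i in 94:122)  pt_of[[local(i)]] <- "Tachycardia"
  for (i in 123:125) pt_of[[local(i)]] <- "Shock"
  for (i in 126:130) pt_of[[local(i)]] <- "Cardiac arrest"
  crs[local(1:80)] <- TRUE      # hypo+tachy and hypo with CRS
  crs[local(94:130)] <- TRUE    # tachy, shock, arrest all with CRS
  anchors <- c("Pyrexia", "Neutropenia", "Headache", "Vomiting", "Seizure",
               "Acute kidney injury")
  for (i in 188:n) pt_of[[i]] <- anchors[((i - 188) %% length(anchors)) + 1]
  crs[188:n] <- (188:n) %% 3 == 0

  reac <- tibble(
    primaryid = rep(pid, lengths(pt_of)),
    caseid = rep(cid, lengths(pt_of)),
    pt = unlist(pt_of)
  )
  sel <- which(crs)
  reac <- bind_rows(reac, tibble(primaryid = pid[sel], caseid = cid[sel],
                                 pt = crs_pt))

  # drugs: target product for everyone, plus deterministic co-medications
  brand <- ifelse(seq_len(n) %% 2 == 0, "KYMRIAH", "TISAGENLECLEUCEL")
  drug <- tibble(primaryid = pid, caseid = cid, drug_seq = "1",
                 role_cod = "PS", drugname = brand,
                 prod_ai = "TISAGENLECLEUCEL")
  co <- list()
  nseq <- rep(1L, n)
  add_co <- function(ix, name) {
    nseq[ix] <<- nseq[ix] + 1L
    co[[length(co) + 1L]] <<- tibble(
      primaryid = pid[ix], caseid = cid[ix],
      drug_seq = as.character(nseq[ix]), role_cod = "C",
      drugname = name, prod_ai = name)
  }
  add_co(which(is_cvae)[seq(1, 187, by = 4)], "LEVETIRACETAM")
  add_co(seq(3, n, by = 10), "SALBUTAMOL")
  add_co(seq(2, n, by = 3), "DEXAMETHASONE")
  add_co(seq(5, n, by = 7), "VANCOMYCIN")
  drug <- bind_rows(c(list(drug), co))

  ther <- tibble(primaryid = pid, caseid = cid, dsg_drug_seq = "1",
                 start_dt = format(start, "%Y%m%d"))
  has_outc <- is_fatal | (seq_len(n) %% 2 == 0)
  outc <- tibble(primaryid = pid[has_outc], caseid = cid[has_outc],
                 outc_cod = ifelse(is_fatal[has_outc], "DE", "HO"))

  cohort_bundle <- assemble_quarter(demo, drug, reac, outc, ther)

  if (n_background > 0) {
    bg_cfg <- generator_config(
      seed = 20230401L, n_reports = as.integer(n_background),
      target_share = 0, injected_ror = setNames(numeric(0), character(0)),
      duplicate_rate = 0, deletion_rate = 0
    )
    bg <- generate_reports(bg_cfg)$bundle
    merge_quarters(list(cohort_bundle, bg))
  } else {
    cohort_bundle
  }
}
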