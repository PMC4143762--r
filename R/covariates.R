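#' @include partition-score.R
NULL

#' Summarize longitudinal visit records to one value per subject
#'
#' Collapses up-to-k per-visit measurements of one covariate or outcome into
#' a single per-subject value: the mean over non-missing visits (age, SBP,
#' DBP) or the sum over non-missing visits (smoking and medication
#' indicators). A subject with no non-missing visit gets `NA`, which later
#' propagates through complete-case filtering — it is not an error.
#'
#' @param values numeric vector of per-visit values for one subject (may
#'   contain `NA`).
#' @param method `"mean"` or `"sum"`.
#' @return a single number, or `NA` if every visit is missing.
#' @examples
#' summarizeLongitudinal(c(30, 32, NA, 34), "mean")  # 32
#' summarizeLongitudinal(c(1, 1, 0, NA), "sum")      # 2
#' @export
summarizeLongitudinal <- function(values, method = c("mean", "sum")) {
  method <- match.arg(method)
  v <- values[!is.na(values)]
  if (length(v) == 0L) return(NA_real_)
  if (method == "mean") mean(v) else sum(v)
}

#' Discretize a summarized covariate into partition levels
#'
#' Converts per-subject summarized covariate values into the categorical
#' levels the partition score consumes.
#'
#' Schemes:
#' \describe{
#'   \item{`tertile`}{empirical tertiles (quantiles at 1/3 and 2/3, linear
#'     interpolation of order statistics, `type = 7`) split subjects into
#'     levels 0/1/2; assignment is right-closed (value <= lower breakpoint
#'     gets 0, <= upper gets 1, else 2). Used for continuous covariates such
#'     as mean age; the breakpoints are data-derived, not fixed.}
#'   \item{`count`}{visit-count recode for summed binary indicators
#'     (smoking, medication): 0 maps to 0, 1 to 1, and 2 or more to 2.}
#'   \item{`binary`}{a two-level factor (gender) passed through, recoded to
#'     0/1 in sorted order of the original codes. Level order is cosmetic:
#'     the partition score is label-invariant.}
#' }
#' `NA` values pass through as `NA` under every scheme.
#'
#' @param values numeric (or, for `binary`, any atomic) per-subject vector.
#' @param scheme `"tertile"`, `"count"` or `"binary"`.
#' @param name factor name used in error messages.
#' @return integer vector of levels in \{0,1,2\} (or \{0,1\} for binary).
#' @examples
#' discretizeEnv(c(0, 1, 2, 3, 4), "count")            # 0 1 2 2 2
#' discretizeEnv(1:9, "tertile")                       # 0 0 0 1 1 1 2 2 2
#' @export
discretizeEnv <- function(values, scheme = c("tertile", "count", "binary"),
                          name = "covariate") {
  scheme <- match.arg(scheme)
  ok <- !is.na(values)
  out <- rep(NA_integer_, length(values))
  if (!any(ok)) return(out)
  v <- values[ok]
  lev <- switch(scheme,
    tertile = {
      if (length(unique(v)) < 3L) {
        stop(sprintf("tertile discretization of '%s' needs at least 3 distinct values", name))
      }
      br <- stats::quantile(v, c(1, 2) / 3, names = FALSE, type = 7)
      ifelse(v <= br[1L], 0L, ifelse(v <= br[2L], 1L, 2L))
    },
    count = {
      if (any(v < 0) || any(v != round(v))) {
        stop(sprintf("count recode of '%s' needs nonnegative integer counts", name))
      }
      as.integer(pmin(v, 2))
    },
    binary = {
      u <- sort(unique(v))
      if (length(u) > 2L) {
        stop(sprintf("binary recode of '%s' found %d levels", name, length(u)))
      }
      as.integer(match(v, u) - 1L)
    }
  )
  out[ok] <- lev
  out
}

#' Code biallelic genotype calls as minor-allele dosage
#'
#' Converts one SNP's calls across subjects to 0/1/2 copies of the minor
#' allele, where the minor allele is the less frequent allele *in the
#' analyzed sample*. Accepts either numeric alternate-allele dosages (as
#' from a VCF) or character calls such as `"AA"`, `"A/G"`, `"C|T"`.
#' If the alternate/second allele turns out to be the more frequent one the
#' coding is flipped (`2 - dosage`); at an exact 50/50 tie the reference
#' (first) allele is treated as major, so the coding is kept. Missing calls
#' propagate as `NA`. A site with more than two observed alleles is not
#' codable: the function warns and returns `NULL` so callers can skip it.
#'
#' @param calls numeric dosages in \{0,1,2,NA\} or character diploid calls.
#' @return integer vector of minor-allele dosages, or `NULL` for a
#'   multi-allelic site.
#' @examples
#' codeGenotypes(c("AA", "AA", "AA", "Aa"))  # 0 0 0 1
#' codeGenotypes(c(2, 2, 1, 0))              # flipped: 0 0 1 2
#' @export
codeGenotypes <- function(calls) {
  if (is.numeric(calls)) {
    d <- as.integer(calls)
    if (any(!is.na(d) & !(d %in% 0:2))) stop("numeric dosages must be 0, 1, 2 or NA")
  } else {
    s <- as.character(calls)
    s <- gsub("[/|]", "", s)
    s[is.na(s) | s == "" | s == ".." | s == "."] <- NA
    if (any(!is.na(s) & nchar(s) != 2L)) {
      stop("character calls must be diploid (two alleles per subject)")
    }
    a1 <- substr(s, 1L, 1L); a2 <- substr(s, 2L, 2L)
    alleles <- unique(stats::na.omit(c(a1, a2)))
    if (length(alleles) > 2L) {
      warning("multi-allelic site skipped (", length(alleles), " alleles observed)")
      return(NULL)
    }
    if (length(alleles) == 0L) return(rep(NA_integer_, length(calls)))
    # count copies of the second allele (first observed allele acts as reference)
    ref <- alleles[1L]
    d <- (a1 != ref) + (a2 != ref)
    d <- as.integer(d)
  }
  # flip so the dosage counts the minor allele; tie keeps reference as major
  freq <- mean(d, na.rm = TRUE) / 2
  if (!is.nan(freq) && freq > 0.5) d <- 2L - d
  d
}

#' Build the per-subject analysis table from longitudinal records
#'
#' Turns the long-format phenotype/covariate table (one row per subject per
#' visit) into one row per subject: covariates summarized over available
#' visits (mean age; summed smoking and medication indicators), outcomes
#' averaged (SBP, DBP), and environment partition labels attached
#' (`env_age` by empirical tertiles, `env_smoke` and `env_medicine` by the
#' 0/1/2+ count recode, `env_gender` binary). A subject missing a single
#' covariate keeps its row with `NA` in the corresponding fields and is
#' dropped only from tests involving that covariate.
#'
#' @param pheno data.frame in the layout returned by [readPhenotypes()]:
#'   columns `subject_id`, `pedigree_id`, `visit`, `age`, `smoke`,
#'   `medicine`, `gender`, `SBP`, `DBP`.
#' @return data.frame with one row per subject: `subject_id`, `pedigree_id`,
#'   `gender`, `age_mean`, `smoke_sum`, `med_sum`, `sbp_mean`, `dbp_mean`,
#'   and the discretized labels `env_age`, `env_smoke`, `env_medicine`,
#'   `env_gender`.
#' @export
buildSubjectTable <- function(pheno) {
  need <- c("subject_id", "pedigree_id", "visit", "age", "smoke",
            "medicine", "gender", "SBP", "DBP")
  miss <- setdiff(need, names(pheno))
  if (length(miss)) stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  sid <- as.character(pheno$subject_id)
  ids <- unique(sid)
  ped <- vapply(ids, function(i) {
    p <- unique(as.character(pheno$pedigree_id[sid == i]))
    if (length(p) != 1L) stop("subject ", i, " has conflicting pedigree ids")
    p
  }, character(1))
  summ <- function(col, method) {
    vapply(ids, function(i) summarizeLongitudinal(pheno[[col]][sid == i], method),
           numeric(1))
  }
  gender <- vapply(ids, function(i) {
    g <- unique(stats::na.omit(pheno$gender[sid == i]))
    if (length(g) > 1L) stop("subject ", i, " has conflicting gender codes")
    if (length(g)) as.character(g) else NA_character_
  }, character(1))
  out <- data.frame(
    subject_id = ids,
    pedigree_id = ped,
    gender = gender,
    age_mean = summ("age", "mean"),
    smoke_sum = summ("smoke", "sum"),
    med_sum = summ("medicine", "sum"),
    sbp_mean = summ("SBP", "mean"),
    dbp_mean = summ("DBP", "mean"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$env_age <- discretizeEnv(out$age_mean, "tertile", name = "age")
  out$env_smoke <- discretizeEnv(out$smoke_sum, "count", name = "smoke")
  out$env_medicine <- discretizeEnv(out$med_sum, "count", name = "medicine")
  out$env_gender <- discretizeEnv(out$gender, "binary", name = "gender")
  out
}
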