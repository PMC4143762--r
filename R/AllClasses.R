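#' @include AllGenerics.R
NULL

#' Joint, marginal, and interaction partition scores for one SNP-environment pair
#'
#' Container for the four partition scores of a single genotype x environment
#' x phenotype triple: the total score over the joint cells, the two marginal
#' scores, and the interaction score (total minus the larger marginal),
#' together with the joint contingency table and the number of complete-case
#' subjects scored.
#'
#' The interaction score may be negative (e.g. for additive or null data);
#' it is stored as computed, never truncated at zero, so that permutation
#' reference distributions are honest.
#'
#' @slot IT numeric(1), total score over the joint genotype x environment cells.
#' @slot IG numeric(1), genotype-marginal score.
#' @slot IE numeric(1), environment-marginal score.
#' @slot IGxE numeric(1), interaction score `IT - max(IG, IE)`.
#' @slot cellCounts table of joint cell counts (genotype level x environment level).
#' @slot nUsed integer(1), subjects entering the computation after
#'   complete-case filtering.
#'
#' @seealso [gxeScores()] which constructs these objects, [partitionScore()]
#'   for the underlying score.
#' @export
setClass("GxEScores",
  representation(
    IT = "numeric",
    IG = "numeric",
    IE = "numeric",
    IGxE = "numeric",
    cellCounts = "table",
    nUsed = "integer"
  )
)

setValidity("GxEScores", function(object) {
  msg <- character(0)
  for (s in c("IT", "IG", "IE", "IGxE")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) {
      msg <- c(msg, sprintf("slot '%s' must be a single finite number", s))
    }
  }
  if (length(msg) == 0L) {
    if (object@IT < -1e-12 || object@IG < -1e-12 || object@IE < -1e-12) {
      msg <- c(msg, "IT, IG, IE must be nonnegative")
    }
    if (abs(object@IGxE - (object@IT - max(object@IG, object@IE))) > 1e-9) {
      msg <- c(msg, "IGxE must equal IT - max(IG, IE)")
    }
    if (sum(object@cellCounts) != object@nUsed) {
      msg <- c(msg, "cell counts must sum to nUsed")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname score-accessors
#' @export
setMethod("scoreTotal", "GxEScores", function(object) object@IT)

#' @rdname score-accessors
#' @export
setMethod("scoreG", "GxEScores", function(object) object@IG)

#' @rdname score-accessors
#' @export
setMethod("scoreE", "GxEScores", function(object) object@IE)

#' @rdname score-accessors
#' @export
setMethod("scoreGxE", "GxEScores", function(object) object@IGxE)

#' @rdname score-accessors
#' @export
setMethod("cellCounts", "GxEScores", function(object) object@cellCounts)

#' @rdname score-accessors
#' @export
setMethod("nUsed", "GxEScores", function(object) object@nUsed)

setMethod("show", "GxEScores", function(object) {
  cat("GxEScores (partition-based interaction scores)\n")
  cat(sprintf("  n used: %d subjects in %d x %d observed cells\n",
              object@nUsed, nrow(object@cellCounts), ncol(object@cellCounts)))
  cat(sprintf("  I_T   = %.6g\n  I_G   = %.6g\n  I_E   = %.6g\n  I_GxE = %.6g\n",
              object@IT, object@IG, object@IE, object@IGxE))
})

#' Hard-call genotype dosage matrix
#'
#' SNP x subject matrix of minor/alternate-allele dosages in \{0, 1, 2, NA\},
#' with per-SNP metadata (id, chromosome, 1-based position, ref/alt alleles).
#' Subject column order is fixed and shared by every SNP row; alignment with
#' phenotype tables is always by subject id, never by position.
#'
#' @slot info data.frame with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`.
#' @slot mat integer matrix (SNPs x subjects) with values 0, 1, 2 or NA;
#'   rownames are SNP ids, colnames subject ids.
#'
#' @seealso [readVCF()], [readDosage()], [writeVCF()]
#' @export
setClass("GenotypeMatrix",
  representation(info = "data.frame", mat = "matrix")
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character(0)
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(object@info))) {
    msg <- c(msg, sprintf("info must have columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(object@info) != nrow(object@mat)) {
    msg <- c(msg, "info rows must match dosage rows")
  }
  vals <- object@mat[!is.na(object@mat)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L))) {
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  if (is.null(colnames(object@mat))) {
    msg <- c(msg, "dosage matrix must carry subject ids as colnames")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname genotype-accessors
#' @export
setMethod("dosage", "GenotypeMatrix", function(object) object@mat)

#' @rdname genotype-accessors
#' @export
setMethod("snpInfo", "GenotypeMatrix", function(object) object@info)

#' @rdname genotype-accessors
#' @export
setMethod("subjectIds", "GenotypeMatrix", function(object) colnames(object@mat))

#' @rdname genotype-accessors
#' @export
setMethod("nSnps", "GenotypeMatrix", function(object) nrow(object@mat))

#' @rdname genotype-accessors
#' @export
setMethod("nSubjects", "GenotypeMatrix", function(object) ncol(object@mat))

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d SNPs x %d subjects\n",
              nrow(object@mat), ncol(object@mat)))
  nmiss <- sum(is.na(object@mat))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nmiss,
              100 * nmiss / max(1, length(object@mat))))
  if (nrow(object@info)) {
    cat("  first SNPs:", paste(utils::head(object@info$snp_id, 3), collapse = ", "),
        if (nrow(object@info) > 3) "..." else "", "\n")
  }
})

#' Constructor for GenotypeMatrix
#'
#' @param mat numeric/integer SNP x subject matrix of dosages in \{0,1,2,NA\};
#'   colnames are subject ids.
#' @param info data.frame of per-SNP metadata (`snp_id`, `chrom`, `pos`,
#'   `ref`, `alt`); defaults are synthesized from rownames when omitted.
#' @return a [GenotypeMatrix-class] object.
#' @export
genotypeMatrix <- function(mat, info = NULL) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (is.null(info)) {
    ids <- rownames(mat)
    if (is.null(ids)) ids <- sprintf("snp%d", seq_len(nrow(mat)))
    info <- data.frame(snp_id = ids, chrom = "1", pos = seq_len(nrow(mat)),
                       ref = "A", alt = "B", stringsAsFactors = FALSE)
  }
  rownames(mat) <- info$snp_id
  methods::new("GenotypeMatrix", info = info, mat = mat)
}

#' Simulated pedigree cohort
#'
#' A synthetic study cohort: per-subject table (id, pedigree, environment
#' level, phenotype), a simulated genotype matrix, the index of the causal
#' SNP (if the generating model has one), and the generating parameters.
#'
#' @slot subjects data.frame with columns `subject_id`, `pedigree_id`,
#'   `env` (level in 0/1/2) and `y` (quantitative phenotype).
#' @slot genotypes a [GenotypeMatrix-class] of simulated SNPs.
#' @slot causal integer(1), row index of the causal SNP, or NA under the null.
#' @slot config list, the validated simulation configuration.
#'
#' @seealso [simulateCohort()], [simConfig()]
#' @export
setClass("SimCohort",
  representation(
    subjects = "data.frame",
    genotypes = "GenotypeMatrix",
    causal = "integer",
    config = "list"
  )
)

setValidity("SimCohort", function(object) {
  msg <- character(0)
  need <- c("subject_id", "pedigree_id", "env", "y")
  if (!all(need %in% names(object@subjects))) {
    msg <- c(msg, sprintf("subjects must have columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(object@subjects) != ncol(object@genotypes@mat)) {
    msg <- c(msg, "subject rows must match genotype columns")
  }
  if (!is.na(object@causal) &&
      (object@causal < 1L || object@causal > nrow(object@genotypes@mat))) {
    msg <- c(msg, "causal SNP index out of range")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname cohort-accessors
#' @export
setMethod("subjectTable", "SimCohort", function(object) object@subjects)

#' @rdname genotype-accessors
#' @export
setMethod("dosage", "SimCohort", function(object) object@genotypes@mat)

#' @rdname cohort-accessors
#' @export
setMethod("causalSnp", "SimCohort", function(object) object@causal)

#' @rdname cohort-accessors
#' @export
setMethod("simParams", "SimCohort", function(object) object@config)

#' Extract the genotype container from a cohort
#' @param object a [SimCohort-class]
#' @return the [GenotypeMatrix-class] slot
#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))

#' @rdname genotypes
#' @export
setMethod("genotypes", "SimCohort", function(object) object@genotypes)

setMethod("show", "SimCohort", function(object) {
  cat(sprintf("SimCohort: %d subjects in %d pedigrees, %d SNPs, model '%s'\n",
              nrow(object@subjects),
              length(unique(object@subjects$pedigree_id)),
              nrow(object@genotypes@mat),
              object@config$model))
  if (!is.na(object@causal)) {
    cat(sprintf("  causal SNP: row %d (%s)\n", object@causal,
                object@genotypes@info$snp_id[object@causal]))
  }
})
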