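#' @include AllGenerics.R
NULL

#' Accessors for partition-score objects
#'
#' Extract the total, marginal, and interaction scores, the joint
#' genotype-by-environment cell counts, and the number of subjects that
#' entered a computation.
#'
#' @param object a [GxEScores-class] object (or, for `nUsed`, any object
#'   carrying a subject count).
#' @return `scoreTotal`, `scoreG`, `scoreE`, `scoreGxE` return a single
#'   numeric score; `cellCounts` returns the genotype x environment
#'   contingency table of counts; `nUsed` returns an integer.
#' @name score-accessors
#' @aliases scoreTotal scoreG scoreE scoreGxE cellCounts nUsed
#' @examples
#' s <- gxeScores(rnorm(30), sample(0:2, 30, TRUE), sample(0:2, 30, TRUE))
#' scoreGxE(s)
#' cellCounts(s)
NULL

#' @rdname score-accessors
#' @export
setGeneric("scoreTotal", function(object) standardGeneric("scoreTotal"))

#' @rdname score-accessors
#' @export
setGeneric("scoreG", function(object) standardGeneric("scoreG"))

#' @rdname score-accessors
#' @export
setGeneric("scoreE", function(object) standardGeneric("scoreE"))

#' @rdname score-accessors
#' @export
setGeneric("scoreGxE", function(object) standardGeneric("scoreGxE"))

#' @rdname score-accessors
#' @export
setGeneric("cellCounts", function(object) standardGeneric("cellCounts"))

#' @rdname score-accessors
#' @export
setGeneric("nUsed", function(object) standardGeneric("nUsed"))

#' Accessors for genotype containers
#'
#' @param object a [GenotypeMatrix-class] or [SimCohort-class] object.
#' @return `dosage` returns the SNP x subject integer dosage matrix;
#'   `snpInfo` the per-SNP metadata data.frame; `subjectIds` the subject
#'   identifiers in column order; `nSnps`/`nSubjects` the dimensions.
#' @name genotype-accessors
#' @aliases dosage snpInfo subjectIds nSnps nSubjects
NULL

#' @rdname genotype-accessors
#' @export
setGeneric("dosage", function(object) standardGeneric("dosage"))

#' @rdname genotype-accessors
#' @export
setGeneric("snpInfo", function(object) standardGeneric("snpInfo"))

#' @rdname genotype-accessors
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))

#' @rdname genotype-accessors
#' @export
setGeneric("nSnps", function(object) standardGeneric("nSnps"))

#' @rdname genotype-accessors
#' @export
setGeneric("nSubjects", function(object) standardGeneric("nSubjects"))

#' Accessors for simulated cohorts
#'
#' @param object a [SimCohort-class] object.
#' @return `subjectTable` returns the per-subject data.frame (ids, pedigree,
#'   environment level, phenotype); `causalSnp` the row index of the causal
#'   SNP in the genotype matrix (`NA` under the null model); `simParams` the
#'   generating configuration.
#' @name cohort-accessors
#' @aliases subjectTable causalSnp simParams
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("subjectTable", function(object) standardGeneric("subjectTable"))

#' @rdname cohort-accessors
#' @export
setGeneric("causalSnp", function(object) standardGeneric("causalSnp"))

#' @rdname cohort-accessors
#' @export
setGeneric("simParams", function(object) standardGeneric("simParams"))
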