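#' @include AllClasses.R
NULL

.missingCodes <- c("NA", ".", "")

#' Read hard-call genotypes from a VCF file
#'
#' Parses a VCF 4.x file (GT field) into a [GenotypeMatrix-class] of
#' alternate-allele dosages: `0/0` maps to 0, `0/1` and `1/0` to 1, `1/1`
#' to 2; phased separators (`|`) are equivalent; `./.` and half-calls map
#' to missing. Multi-allelic records are skipped with a message reporting
#' the count. Coordinates stay 1-based as in the VCF.
#'
#' Dosages are alt-allele counts as stored; recode per analyzed sample with
#' [codeGenotypes()] (done automatically inside [runScan()] inputs built by
#' this package's pipeline if desired).
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @return a [GenotypeMatrix-class].
#' @export
readVCF <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(cnd) stop("unreadable VCF '", path, "': ",
                                           conditionMessage(cnd)))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
  if (any(multi)) {
    message(sum(multi), " multi-allelic record(s) skipped")
  }
  keep <- which(!multi)
  if (length(keep) == 0L) stop("no usable biallelic records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  # alt-allele count; any missing or half-called allele makes the call missing
  core <- sub(":.*", "", gt)
  dos <- matrix(NA_integer_, nrow(core), ncol(core),
                dimnames = dimnames(core))
  dos[core %in% c("0/0", "0|0")] <- 0L
  dos[core %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[core %in% c("1/1", "1|1")] <- 2L
  ids <- fix$ID
  bad <- is.na(ids) | ids == "."
  ids[bad] <- sprintf("%s:%s", fix$CHROM[bad], fix$POS[bad])
  info <- data.frame(snp_id = ids, chrom = fix$CHROM,
                     pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  genotypeMatrix(dos, info)
}

#' Read genotypes from the simple dosage-matrix TSV dialect
#'
#' Tab-separated text with header columns `snp_id`, `chrom`, `pos` followed
#' by one column per subject holding dosages in \{0,1,2\}; `NA`, `.` and
#' empty cells are missing. This dialect is the fixture-friendly
#' alternative to VCF.
#'
#' @param path path to the TSV file.
#' @return a [GenotypeMatrix-class].
#' @export
readDosage <- function(path) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         na.strings = .missingCodes, check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("dosage file lacks columns: ", paste(miss, collapse = ", "))
  subjCols <- setdiff(names(d), need)
  if (length(subjCols) == 0L) stop("dosage file has no subject columns")
  mat <- as.matrix(d[, subjCols, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- d$snp_id
  info <- data.frame(snp_id = d$snp_id, chrom = as.character(d$chrom),
                     pos = as.integer(d$pos), ref = "A", alt = "B",
                     stringsAsFactors = FALSE)
  genotypeMatrix(mat, info)
}

#' Read the long-format phenotype/covariate table
#'
#' Delimited text (tab or comma, sniffed from the header line) with one row
#' per subject per visit and header columns `subject_id`, `pedigree_id`,
#' `visit`, `age`, `smoke`, `medicine`, `gender`, `SBP`, `DBP`. Unknown
#' extra columns are preserved. Missing value codes are `NA`, `.` and the
#' empty string.
#'
#' Validation: a missing required column, a duplicated (subject, visit)
#' pair, a subject with conflicting pedigree ids, or more visits per
#' subject than `maxVisits` is a hard error.
#'
#' @param path path to the file.
#' @param maxVisits maximum visits per subject (default 4).
#' @return validated data.frame in long format.
#' @export
readPhenotypes <- function(path, maxVisits = 4L) {
  if (!file.exists(path)) stop("cannot read phenotype table: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  d <- utils::read.delim(path, sep = sep, header = TRUE,
                         na.strings = .missingCodes,
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject_id", "pedigree_id", "visit", "age", "smoke",
            "medicine", "gender", "SBP", "DBP")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  key <- paste(d$subject_id, d$visit, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- d$subject_id[duplicated(key)]
    stop("duplicate (subject, visit) rows for: ",
         paste(unique(utils::head(dup, 5)), collapse = ", "))
  }
  nped <- tapply(as.character(d$pedigree_id), as.character(d$subject_id),
                 function(p) length(unique(p)))
  if (any(nped > 1L)) {
    stop("conflicting pedigree ids for subject(s): ",
         paste(utils::head(names(nped)[nped > 1L], 5), collapse = ", "))
  }
  nv <- table(d$subject_id)
  if (any(nv > maxVisits)) {
    stop("subject(s) exceed ", maxVisits, " visits: ",
         paste(utils::head(names(nv)[nv > maxVisits], 5), collapse = ", "))
  }
  d
}

#' Write scan results as TSV
#'
#' One header line, tab-separated, newline-terminated; column order exactly
#' as produced by [runScan()]. Scores are printed with 6 significant
#' digits, p-values in scientific notation with 6 significant digits,
#' missing values as `NA`.
#'
#' @param results data.frame from [runScan()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeResults <- function(results, path) {
  out <- results
  for (col in names(out)) {
    if (col %in% c("I_T", "I_G", "I_E", "I_GxE")) {
      out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                           formatC(out[[col]], digits = 6, format = "g"))
    } else if (startsWith(col, "p_")) {
      out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                           formatC(out[[col]], digits = 6, format = "e"))
    }
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  ok <- tryCatch({
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    TRUE
  }, error = function(cnd) {
    warning("partial results flushed to ", path)
    stop("failed writing results: ", conditionMessage(cnd))
  })
  invisible(path)
}

#' Read back a scan results TSV
#'
#' @param path path written by [writeResults()].
#' @return data.frame with numeric score and p-value columns.
#' @export
readResults <- function(path) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         na.strings = "NA", stringsAsFactors = FALSE)
  for (col in intersect(c("I_T", "I_G", "I_E", "I_GxE"), names(d))) {
    d[[col]] <- as.numeric(d[[col]])
  }
  for (col in grep("^p_", names(d), value = TRUE)) d[[col]] <- as.numeric(d[[col]])
  d
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits an uncompressed VCFv4.2 file with GT-only genotype columns
#' (`0/0`, `0/1`, `1/1`, `./.`), suitable as a simulation fixture and
#' round-trippable through [readVCF()].
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeVCF <- function(genotypes, path) {
  stopifnot(methods::is(genotypes, "GenotypeMatrix"))
  info <- snpInfo(genotypes)
  mat <- dosage(genotypes)
  gtStr <- matrix(c("0/0", "0/1", "1/1")[mat + 1L], nrow(mat), ncol(mat))
  gtStr[is.na(mat)] <- "./."
  hdr <- c("##fileformat=VCFv4.2",
           "##source=pbiScan-simulator",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(mat)), collapse = "\t"))
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(info$chrom[i], info$pos[i], info$snp_id[i], info$ref[i],
            info$alt[i], ".", "PASS", ".", "GT", gtStr[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a simulated cohort's phenotype table
#'
#' Writes the per-subject table of a [SimCohort-class] in the long-format
#' layout [readPhenotypes()] accepts (one visit per subject; the simulated
#' environment level is carried in the extra column `env`).
#'
#' @param cohort a [SimCohort-class].
#' @param path output path (tab-separated).
#' @return the path, invisibly.
#' @export
writeCohortPhenotypes <- function(cohort, path) {
  s <- subjectTable(cohort)
  d <- data.frame(subject_id = s$subject_id, pedigree_id = s$pedigree_id,
                  visit = 1L, age = NA, smoke = NA, medicine = NA,
                  gender = NA, SBP = s$y, DBP = s$y, env = s$env, y = s$y,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
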