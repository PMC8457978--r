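# Plain-text readers/writers for the pipeline's exchange formats: a
# subjects x SNPs dosage TSV (0/1/2, missing "NA"), PLINK-compatible
# .ped/.map text, and a covariate/exposure TSV with a header row.

#' Write and read a dosage TSV
#'
#' Subjects x variants table of additive minor-allele dosages (0/1/2, missing
#' written as `NA`), first column `subject_id`, one column per variant id.
#' Variant metadata travels in a sidecar `<path>.meta` TSV
#' (id, chr, pos, minor, major).
#'
#' @param gm a `genotype_matrix`.
#' @param path output file path.
#' @return `write_dosage_tsv` the path, invisibly; `read_dosage_tsv` a
#'   `genotype_matrix`.
#' @export
write_dosage_tsv <- function(gm, path) {
  df <- data.frame(subject_id = gm$subject_ids, gm$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gm$variant_meta, paste0(path, ".meta"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta")
  dosage <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(dosage) <- "integer"
  meta <- if (file.exists(meta_path)) {
    utils::read.table(meta_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else {
    data.frame(id = colnames(dosage), chr = NA_integer_, pos = NA_integer_,
               minor = NA_character_, major = NA_character_,
               stringsAsFactors = FALSE)
  }
  structure(list(dosage = dosage, variant_meta = meta,
                 subject_ids = as.character(df[[1]])),
            class = "genotype_matrix")
}

#' Write and read PLINK-style .ped/.map text files
#'
#' `write_ped_map` emits `<prefix>.ped` (FID IID PAT MAT SEX PHENO followed
#' by two allele columns per variant, `0 0` for missing) and `<prefix>.map`
#' (chr, id, 0, position). Dosage d codes d copies of the minor allele.
#' `read_ped_map` inverts the encoding back to minor-allele dosage using the
#' .map order and the per-variant allele labels observed in the file
#' (orientation is recomputed: the rarer observed allele is coded as minor).
#'
#' @param gm a `genotype_matrix`.
#' @param prefix output path prefix.
#' @param phenotype optional 0/1 case vector, written as 1/2 in PLINK
#'   convention (2 = case, 0 = unknown when omitted).
#' @return `write_ped_map` the prefix, invisibly; `read_ped_map` a list with
#'   a `genotype_matrix` and the phenotype vector (0/1 or NA).
#' @export
write_ped_map <- function(gm, prefix, phenotype = NULL) {
  meta <- gm$variant_meta
  n <- nrow(gm$dosage); m <- ncol(gm$dosage)
  ph <- if (is.null(phenotype)) rep(0L, n) else phenotype + 1L
  allele_cols <- matrix("0", n, 2L * m)
  for (j in seq_len(m)) {
    d <- gm$dosage[, j]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, meta$minor[j], meta$major[j]))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2L, meta$minor[j], meta$major[j]))
    allele_cols[, 2L * j - 1L] <- a1
    allele_cols[, 2L * j] <- a2
  }
  ped <- cbind(gm$subject_ids, gm$subject_ids, "0", "0", "0", ph, allele_cols)
  utils::write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  map <- data.frame(meta$chr, meta$id, 0L, meta$pos)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_ped_map
#' @export
read_ped_map <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                           stringsAsFactors = FALSE)
  names(map) <- c("chr", "id", "cm", "pos")
  ped <- utils::read.table(paste0(prefix, ".ped"), sep = " ",
                           stringsAsFactors = FALSE, colClasses = "character")
  m <- nrow(map)
  n <- nrow(ped)
  dosage <- matrix(NA_integer_, n, m)
  minor <- major <- character(m)
  for (j in seq_len(m)) {
    a1 <- ped[[6L + 2L * j - 1L]]
    a2 <- ped[[6L + 2L * j]]
    ok <- a1 != "0" & a2 != "0"
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    if (length(alleles) == 0L) { minor[j] <- major[j] <- NA_character_; next }
    counts <- vapply(alleles, function(a) sum(a1[ok] == a) + sum(a2[ok] == a),
                     numeric(1))
    minor[j] <- alleles[which.min(counts)]
    major[j] <- alleles[which.max(counts)]
    if (length(alleles) == 1L) major[j] <- minor[j]
    dosage[ok, j] <- (a1[ok] == minor[j]) + (a2[ok] == minor[j])
  }
  colnames(dosage) <- map$id
  ph_raw <- as.integer(ped[[6]])
  phenotype <- ifelse(ph_raw %in% c(1L, 2L), ph_raw - 1L, NA_integer_)
  gm <- structure(
    list(dosage = dosage,
         variant_meta = data.frame(id = map$id, chr = map$chr, pos = map$pos,
                                   minor = minor, major = major,
                                   stringsAsFactors = FALSE),
         subject_ids = ped[[2]]),
    class = "genotype_matrix")
  list(genotypes = gm, phenotype = phenotype)
}

#' Write and read the covariate/exposure TSV
#'
#' One row per subject, header row, first column `subject_id`.
#'
#' @param covariates data frame of covariates and exposures.
#' @param subject_ids character vector matching the rows.
#' @param path file path.
#' @return the path (write) or a data frame with `subject_id` first (read).
#' @export
write_covariates_tsv <- function(covariates, subject_ids, path) {
  df <- data.frame(subject_id = subject_ids, covariates,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariates_tsv
#' @export
read_covariates_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
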