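SUMSTAT_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n")
BASES <- c("A", "C", "G", "T")

#' Construct a GWAS summary-statistics object
#'
#' A `summary_stats` object holds one trait's per-SNP association records:
#' rsID, genomic position (1-based), effect and other allele (single bases),
#' effect-allele frequency, per-allele effect estimate with its standard
#' error, p-value and sample size. Records are kept in input order and must
#' be unique on `snp_id`.
#'
#' @param trait_name Non-empty trait label.
#' @param records Data frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @return An object of class `summary_stats` with elements `trait_name`
#'   and `records`.
#' @export
summary_stats <- function(trait_name, records) {
  stopifnot(is.character(trait_name), length(trait_name) == 1L,
            nzchar(trait_name))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SUMSTAT_COLS, names(records))
  if (length(missing_cols) > 0L)
    stop("summary_stats records missing column(s): ",
         paste(missing_cols, collapse = ", "))
  records <- records[SUMSTAT_COLS]
  if (anyDuplicated(records$snp_id))
    stop("duplicate snp_id in summary statistics for trait '", trait_name, "'")
  rownames(records) <- NULL
  structure(list(trait_name = trait_name, records = records),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("GWAS summary statistics: ", x$trait_name, "\n",
      "  ", nrow(x$records), " records\n", sep = "")
  invisible(x)
}

#' Number of SNP records
#' @param stats A `summary_stats` object.
#' @return Integer record count.
#' @export
n_snps <- function(stats) nrow(stats$records)

# Per-row invariant check; returns logical keep vector plus reasons.
check_record_invariants <- function(rec) {
  ok_allele <- rec$effect_allele %in% BASES & rec$other_allele %in% BASES &
    rec$effect_allele != rec$other_allele
  ok_se   <- is.finite(rec$se) & rec$se > 0
  ok_p    <- is.finite(rec$pval) & rec$pval > 0 & rec$pval <= 1
  ok_eaf  <- is.na(rec$eaf) | (rec$eaf >= 0 & rec$eaf <= 1)
  ok_pos  <- is.finite(rec$pos) & rec$pos >= 1
  ok_n    <- is.finite(rec$n) & rec$n > 0
  ok_beta <- is.finite(rec$beta)
  list(keep = ok_allele & ok_se & ok_p & ok_eaf & ok_pos & ok_n & ok_beta,
       counts = c(invalid_allele = sum(!ok_allele),
                  nonpositive_se = sum(!ok_se),
                  out_of_range_pval = sum(!ok_p),
                  out_of_range_eaf = sum(!ok_eaf),
                  invalid_pos = sum(!ok_pos),
                  invalid_n = sum(!ok_n),
                  invalid_beta = sum(!ok_beta)))
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Reads a tab-delimited file with a header row ('.' decimal, "NA" for
#' missing), optionally remapping column names, upper-cases alleles, drops
#' records violating the per-SNP invariants (non-ACGT or identical alleles,
#' `se <= 0`, p-value outside (0,1], frequency outside \[0,1\]) and records
#' the drop counts in a load report attached as attribute `"load_report"`.
#' Input row order is preserved.
#'
#' @param path File path.
#' @param trait_name Trait label; defaults to the file name without extension.
#' @param column_map Optional named character vector mapping canonical column
#'   names (see [summary_stats()]) to the names used in the file, e.g.
#'   `c(snp_id = "rsid", pval = "p")`. Unmapped canonical names are looked up
#'   verbatim.
#' @return A `summary_stats` object; `attr(, "load_report")` holds
#'   `n_read`, `n_kept`, `n_dropped` and per-failure-class counts.
#' @export
read_summary_stats <- function(path, trait_name = NULL, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA",
                           colClasses = NA, check.names = FALSE)
  if (nrow(raw) == 0L && ncol(raw) == 0L) stop("empty summary-statistics file: ", path)
  wanted <- stats::setNames(SUMSTAT_COLS, SUMSTAT_COLS)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), SUMSTAT_COLS)
    if (length(bad) > 0L)
      stop("column_map names must be canonical column names; unknown: ",
           paste(bad, collapse = ", "))
    wanted[names(column_map)] <- unname(column_map)
  }
  absent <- wanted[!wanted %in% names(raw)]
  if (length(absent) > 0L)
    stop("mandatory column(s) missing from ", path, ": ",
         paste(sprintf("%s (mapped to '%s')", names(absent), absent),
               collapse = ", "))
  rec <- stats::setNames(raw[unname(wanted)], names(wanted))
  rec$snp_id <- as.character(rec$snp_id)
  rec$chrom <- as.character(rec$chrom)
  rec$pos <- as.integer(rec$pos)
  rec$effect_allele <- toupper(as.character(rec$effect_allele))
  rec$other_allele <- toupper(as.character(rec$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n"))
    rec[[col]] <- as.numeric(rec[[col]])

  chk <- check_record_invariants(rec)
  kept <- rec[chk$keep, , drop = FALSE]
  dup <- duplicated(kept$snp_id)
  kept <- kept[!dup, , drop = FALSE]
  if (is.null(trait_name))
    trait_name <- sub("\\.[^.]*$", "", basename(path))
  out <- summary_stats(trait_name, kept)
  attr(out, "load_report") <- c(
    list(n_read = nrow(rec), n_kept = nrow(kept),
         n_dropped = nrow(rec) - nrow(kept),
         duplicate_id = sum(dup)),
    as.list(chk$counts))
  out
}

#' Write GWAS summary statistics to a tab-delimited file
#'
#' Writes the canonical ten-column tab-delimited layout with a header row;
#' missing effect-allele frequencies are serialized as the token `NA`.
#' [read_summary_stats()] on the result reproduces the input field-for-field.
#'
#' @param stats A `summary_stats` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary_stats <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  ok <- tryCatch({
    utils::write.table(stats$records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write summary statistics to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Validate a summary-statistics object
#'
#' Pure reporting operation: counts, without modifying the input, the records
#' that violate each invariant class — duplicate identifiers, non-ACGT or
#' identical alleles, non-positive standard errors, p-values outside (0,1],
#' frequencies outside \[0,1\].
#'
#' @param stats A `summary_stats` object (or a bare record data frame).
#' @return Named list of failure counts.
#' @export
validate_summary_stats <- function(stats) {
  rec <- if (inherits(stats, "summary_stats")) stats$records else stats
  chk <- check_record_invariants(rec)
  c(list(duplicate_id = sum(duplicated(rec$snp_id))), as.list(chk$counts))
}

#' Construct an LD matrix
#'
#' Squared-correlation (r^2) matrix over a set of SNPs. Symmetry, a unit
#' diagonal and values in \[0,1\] are asserted on construction.
#'
#' @param snp_ids Character vector of SNP identifiers (unique).
#' @param r2 Square numeric matrix of squared correlations, rows/columns in
#'   `snp_ids` order.
#' @return An `ld_matrix` object.
#' @export
ld_matrix <- function(snp_ids, r2) {
  snp_ids <- as.character(snp_ids)
  stopifnot(!anyDuplicated(snp_ids))
  r2 <- as.matrix(r2)
  if (nrow(r2) != length(snp_ids) || ncol(r2) != length(snp_ids))
    stop("r2 matrix dimensions do not match snp_ids")
  if (length(snp_ids) > 0L) {
    if (!isTRUE(all.equal(r2, t(r2), tolerance = 1e-8)))
      stop("LD matrix is not symmetric")
    if (any(abs(diag(r2) - 1) > 1e-8))
      stop("LD matrix diagonal must be exactly 1")
    if (any(r2 < -1e-12 | r2 > 1 + 1e-12))
      stop("LD r2 values must lie in [0, 1]")
  }
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, r2 = r2), class = "ld_matrix")
}

#' Read an LD matrix from a tab-delimited file
#'
#' Accepts either a sparse triplet file with columns `snp_a snp_b r2`
#' (unlisted pairs are r^2 = 0) or a square layout whose first column holds
#' SNP ids and whose remaining column names are the same ids.
#'
#' @param path File path.
#' @return An `ld_matrix` object.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("snp_a", "snp_b", "r2") %in% names(tab))) {
    ids <- sort(unique(c(tab$snp_a, tab$snp_b)))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    ia <- match(tab$snp_a, ids); ib <- match(tab$snp_b, ids)
    m[cbind(ia, ib)] <- tab$r2
    m[cbind(ib, ia)] <- tab$r2
    diag(m) <- 1
    return(ld_matrix(ids, m))
  }
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  colnames(m) <- names(tab)[-1L]
  if (!identical(colnames(m), ids))
    stop("square LD file: column names must equal the id column")
  ld_matrix(ids, m)
}

#' Write an LD matrix as a sparse triplet file
#'
#' Emits one `snp_a snp_b r2` row per off-diagonal pair with nonzero r^2
#' (upper triangle only); absent pairs read back as r^2 = 0.
#'
#' @param ld An `ld_matrix` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  idx <- which(upper.tri(ld$r2) & ld$r2 != 0, arr.ind = TRUE)
  # self-pairs keep isolated SNPs present in the file
  out <- rbind(data.frame(snp_a = ld$snp_ids, snp_b = ld$snp_ids, r2 = 1,
                          stringsAsFactors = FALSE),
               data.frame(snp_a = ld$snp_ids[idx[, 1L]],
                          snp_b = ld$snp_ids[idx[, 2L]],
                          r2 = ld$r2[idx],
                          stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# r^2 between two SNP id vectors; ids absent from the matrix are unlinked.
ld_r2 <- function(ld, id_a, id_b) {
  n <- max(length(id_a), length(id_b))
  if (is.null(ld)) return(numeric(n))
  ia <- rep_len(match(id_a, ld$snp_ids), n)
  ib <- rep_len(match(id_b, ld$snp_ids), n)
  out <- numeric(n)
  ok <- !is.na(ia) & !is.na(ib)
  out[ok] <- ld$r2[cbind(ia[ok], ib[ok])]
  out
}
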