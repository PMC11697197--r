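#' @importFrom stats pnorm pchisq pt coef lm median rnorm runif sd setNames
#' @importFrom utils read.delim write.table
NULL

# Standard column set for a GWAS summary-statistics table.
GWAS_COLUMNS <- c("snp", "chr", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n")

#' Construct a GWAS summary-statistics table
#'
#' A `gwas_table` is a data frame with one row per SNP and the standard
#' columns `snp`, `chr`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pval`, `n`, carrying trait metadata as attributes. For a
#' binary trait `beta` is on the log-odds scale. Rows violating the record
#' invariants (`se <= 0`, `pval` outside (0, 1], `eaf` outside [0, 1],
#' identical alleles) are dropped with a count kept in the `provenance`
#' attribute; duplicated `snp` ids keep the row with the smallest p-value.
#'
#' @param data data frame holding the standard columns (missing `eaf` or `n`
#'   columns are filled with `NA`).
#' @param trait_id short identifier for the trait (e.g. a GWAS accession).
#' @param trait_label free-text trait description.
#' @param trait_kind `"continuous"` or `"binary"`.
#' @return A `gwas_table` object.
#' @export
gwas_table <- function(data, trait_id, trait_label = trait_id,
                       trait_kind = c("continuous", "binary")) {
  trait_kind <- match.arg(trait_kind)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (col in c("eaf", "n")) if (!col %in% names(data)) data[[col]] <- NA_real_
  missing_cols <- setdiff(GWAS_COLUMNS, names(data))
  if (length(missing_cols) > 0) {
    stop("gwas_table: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[GWAS_COLUMNS]
  data$snp <- as.character(data$snp)
  data$chr <- as.character(data$chr)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    data[[col]] <- as.numeric(data[[col]])
  }

  n_raw <- nrow(data)
  bad <- is.na(data$snp) | is.na(data$beta) |
    is.na(data$se) | data$se <= 0 |
    is.na(data$pval) | data$pval <= 0 | data$pval > 1 |
    (!is.na(data$eaf) & (data$eaf < 0 | data$eaf > 1)) |
    data$effect_allele == data$other_allele
  data <- data[!bad, , drop = FALSE]
  n_invalid <- sum(bad)

  # duplicates: keep the smallest p-value, ties broken by original order
  data <- data[order(data$pval), , drop = FALSE]
  dup <- duplicated(data$snp)
  n_dup <- sum(dup)
  data <- data[!dup, , drop = FALSE]
  data <- data[order(data$chr, data$pos, data$snp), , drop = FALSE]
  rownames(data) <- NULL

  structure(data,
            trait_id = trait_id,
            trait_label = trait_label,
            trait_kind = trait_kind,
            provenance = list(n_raw = n_raw, n_dropped_invalid = n_invalid,
                              n_dropped_duplicate = n_dup),
            class = c("gwas_table", "data.frame"))
}

#' @export
print.gwas_table <- function(x, ...) {
  cat(sprintf("<gwas_table> %s (%s), %d SNPs\n",
              attr(x, "trait_id"), attr(x, "trait_kind"), nrow(x)))
  NextMethod()
}

#' Trait metadata accessors
#'
#' @param x a `gwas_table`.
#' @return The trait id, label or kind stored on the table.
#' @export
trait_id <- function(x) attr(x, "trait_id")

#' @rdname trait_id
#' @export
trait_kind <- function(x) attr(x, "trait_kind")

#' Read a GWAS summary-statistics table from delimited text
#'
#' Reads a tab-separated file with a header row into a [gwas_table()].
#' Nonstandard headers are mapped through `column_map`, a named character
#' vector from standard names (`snp`, `chr`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`) to the file's headers.
#' Rows failing the record invariants are dropped and counted in the
#' `provenance` attribute; duplicate `snp` ids keep the smallest p-value.
#'
#' @param path file to read.
#' @param trait_id,trait_label,trait_kind trait metadata; see [gwas_table()].
#' @param column_map optional named character vector mapping standard column
#'   names to the file's headers.
#' @param sep field separator, tab by default.
#' @return A `gwas_table`.
#' @export
read_gwas_table <- function(path, trait_id = basename(path),
                            trait_label = trait_id,
                            trait_kind = c("continuous", "binary"),
                            column_map = NULL, sep = "\t") {
  trait_kind <- match.arg(trait_kind)
  raw <- read.delim(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
  if (!is.null(column_map)) {
    absent <- setdiff(unname(column_map), names(raw))
    if (length(absent) > 0) {
      stop("read_gwas_table: mapped column(s) not found in '", path, "': ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    for (std in names(column_map)) raw[[std]] <- raw[[column_map[[std]]]]
  }
  absent <- setdiff(setdiff(GWAS_COLUMNS, c("eaf", "n")), names(raw))
  if (length(absent) > 0) {
    stop("read_gwas_table: missing column(s) in '", path, "': ",
         paste(absent, collapse = ", "),
         "; supply a column_map for nonstandard headers", call. = FALSE)
  }
  tab <- gwas_table(raw, trait_id = trait_id, trait_label = trait_label,
                    trait_kind = trait_kind)
  if (nrow(tab) == 0) {
    stop("read_gwas_table: no valid rows in '", path, "'", call. = FALSE)
  }
  prov <- attr(tab, "provenance")
  if (prov$n_dropped_invalid + prov$n_dropped_duplicate > 0) {
    message(sprintf("read_gwas_table [%s]: dropped %d invalid and %d duplicate rows of %d",
                    trait_id, prov$n_dropped_invalid, prov$n_dropped_duplicate,
                    prov$n_raw))
  }
  tab
}

#' Write a GWAS summary-statistics table to tab-separated text
#'
#' Numeric fields are written with 12 significant digits so that a
#' write/read cycle is the identity; missing `eaf`/`n` are written as `NA`.
#'
#' @param table a `gwas_table`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_gwas_table <- function(table, path) {
  stopifnot(inherits(table, "gwas_table"))
  out <- as.data.frame(table)
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         sprintf("%.12g", out[[col]]))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a linkage-disequilibrium matrix
#'
#' Holds pairwise squared correlations (r-squared) between SNPs, used by the
#' clumping rule. The matrix must be symmetric with a unit diagonal and
#' entries in \[0, 1\].
#'
#' @param snp_ids character vector of SNP identifiers, in matrix order.
#' @param r2 square numeric matrix of squared correlations.
#' @return An `ld_matrix` object (list with `snp_ids` and `r2`).
#' @export
ld_matrix <- function(snp_ids, r2) {
  r2 <- as.matrix(r2)
  stopifnot(length(snp_ids) == nrow(r2), nrow(r2) == ncol(r2))
  if (any(is.na(r2)) || any(r2 < 0) || any(r2 > 1)) {
    stop("ld_matrix: r2 values must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(r2 - t(r2))) > 1e-8) stop("ld_matrix: r2 must be symmetric", call. = FALSE)
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("ld_matrix: diagonal must be 1", call. = FALSE)
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r2 = r2), class = "ld_matrix")
}

#' Read an LD matrix from long-format text
#'
#' Expects a 3-column tab-separated file `snp_a`, `snp_b`, `r2`; pairs not
#' listed are taken as r-squared 0, the diagonal is fixed at 1.
#'
#' @param path file to read.
#' @return An [ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  long <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("snp_a", "snp_b", "r2")
  if (!all(need %in% names(long))) {
    stop("read_ld_matrix: expected columns snp_a, snp_b, r2", call. = FALSE)
  }
  ids <- sort(unique(c(long$snp_a, long$snp_b)))
  r2 <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  r2[cbind(long$snp_a, long$snp_b)] <- long$r2
  r2[cbind(long$snp_b, long$snp_a)] <- long$r2
  diag(r2) <- 1
  ld_matrix(ids, r2)
}
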