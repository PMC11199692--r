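SUMSTATS_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")

#' Construct / validate a GWAS summary-statistics table
#'
#' A \code{sumstats} object is a plain data frame with one row per SNP and
#' columns \code{snp_id, chrom, pos, effect_allele, other_allele, eaf, beta,
#' se, pval, n}, plus a \code{trait_label} attribute. \code{beta} is the
#' per-effect-allele association (log odds ratio for binary traits),
#' \code{se} its standard error, \code{eaf} the effect-allele frequency
#' (may be \code{NA}).
#'
#' @param x A data frame with the columns above.
#' @param trait_label Name of the trait the table describes.
#' @return \code{x} with class \code{c("sumstats", "data.frame")}.
#' @export
as_sumstats <- function(x, trait_label = "trait") {
  missing_cols <- setdiff(SUMSTATS_COLS, names(x))
  if (length(missing_cols))
    stop("sumstats table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  x <- as.data.frame(x)[, SUMSTATS_COLS]
  x$snp_id <- as.character(x$snp_id)
  x$chrom <- as.character(x$chrom)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  attr(x, "trait_label") <- trait_label
  class(x) <- c("sumstats", "data.frame")
  validate_sumstats(x)
}

#' @rdname as_sumstats
#' @export
validate_sumstats <- function(x) {
  probs <- character(0)
  dup <- unique(x$snp_id[duplicated(x$snp_id)])
  if (length(dup))
    probs <- c(probs, paste0("duplicate snp_id: ",
                             paste(utils::head(dup, 5), collapse = ", ")))
  bad_se <- which(!is.finite(x$se) | x$se <= 0)
  if (length(bad_se))
    probs <- c(probs, paste0("non-positive se for snp_id: ",
                             paste(utils::head(x$snp_id[bad_se], 5),
                                   collapse = ", "),
                             " (row ",
                             paste(utils::head(bad_se, 5), collapse = ", "),
                             ")"))
  same <- which(x$effect_allele == x$other_allele)
  if (length(same))
    probs <- c(probs, paste0("effect_allele == other_allele for snp_id: ",
                             paste(utils::head(x$snp_id[same], 5),
                                   collapse = ", ")))
  bad_allele <- which(!(x$effect_allele %in% c("A", "C", "G", "T")) |
                        !(x$other_allele %in% c("A", "C", "G", "T")))
  if (length(bad_allele))
    probs <- c(probs, paste0("non-ACGT allele at row ",
                             paste(utils::head(bad_allele, 5),
                                   collapse = ", ")))
  bad_p <- which(!is.na(x$pval) & (x$pval <= 0 | x$pval > 1))
  if (length(bad_p))
    probs <- c(probs, paste0("pval outside (0, 1] at row ",
                             paste(utils::head(bad_p, 5), collapse = ", ")))
  if (length(probs))
    stop("invalid summary statistics: ", paste(probs, collapse = "; "),
         call. = FALSE)
  x
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' The native dialect has the header
#' \code{snp_id chrom pos effect_allele other_allele eaf beta se pval n}
#' with \code{NA} for missing values. Files with foreign headers are read by
#' supplying \code{column_map}, a named list/vector mapping native names to
#' the file's column names (e.g. \code{list(snp_id = "SNP", beta = "b")}).
#'
#' @param path Path to a TSV file.
#' @param column_map Optional mapping from native column names to the
#'   file's names; may also be the path to a YAML file holding it.
#' @param trait_label Trait name recorded on the result.
#' @return A validated [as_sumstats()] table.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(column_map) && length(column_map) == 1 &&
      file.exists(column_map))
    column_map <- yaml::read_yaml(column_map)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA",
                           check.names = FALSE)
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    missing_src <- setdiff(unname(column_map), names(tab))
    if (length(missing_src))
      stop("column_map refers to absent column(s): ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    for (native in names(column_map))
      names(tab)[names(tab) == column_map[[native]]] <- native
  }
  missing_cols <- setdiff(SUMSTATS_COLS, names(tab))
  if (length(missing_cols))
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), " in ", path, call. = FALSE)
  as_sumstats(tab, trait_label = trait_label %||%
                sub("\\.[^.]*$", "", basename(path)))
}

#' Write summary statistics in the native TSV dialect
#'
#' @param x A \code{sumstats} table.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_sumstats <- function(x, path) {
  utils::write.table(as.data.frame(x)[, SUMSTATS_COLS], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
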