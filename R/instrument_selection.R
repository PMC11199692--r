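#' Filter SNPs by exposure association p-value
#'
#' Retains rows with \code{pval < p_threshold} (strict), preserving input
#' order. The conventional genome-wide threshold 5e-8 is the default.
#'
#' @param stats A [as_sumstats()] table.
#' @param p_threshold Significance threshold.
#' @return The filtered \code{sumstats} table; a warning is raised when
#'   nothing survives.
#' @export
significance_filter <- function(stats, p_threshold = 5e-8) {
  keep <- stats$pval < p_threshold
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out))
    warning("no SNP passes the significance threshold ", p_threshold,
            call. = FALSE)
  attr(out, "trait_label") <- attr(stats, "trait_label")
  class(out) <- class(stats)
  out
}

# r2 lookup helper: `ld` may be a symmetric matrix with snp_id dimnames or a
# data frame (snp_a, snp_b, r2). Missing pairs are treated as r2 = 0.
ld_r2 <- function(ld, a, b) {
  if (is.matrix(ld)) {
    if (a %in% rownames(ld) && b %in% colnames(ld)) return(ld[a, b])
    return(0)
  }
  hit <- (ld$snp_a == a & ld$snp_b == b) | (ld$snp_a == b & ld$snp_b == a)
  if (any(hit)) ld$r2[which(hit)[1]] else 0
}

#' Greedy LD clumping of candidate instruments
#'
#' PLINK-style clumping: candidates are ordered by ascending p-value (ties
#' broken by \code{snp_id}); the best remaining SNP is kept and every other
#' SNP on the same chromosome within \code{window_kb} kilobases whose
#' r-squared with it exceeds \code{r2_max} is removed; repeat until
#' exhausted. The distance window is closed (\code{<= window_kb}).
#' The result is therefore invariant to input row order.
#'
#' @param candidates A \code{sumstats} table (typically the output of
#'   [significance_filter()]).
#' @param ld Pairwise r-squared lookup: a symmetric matrix with snp ids as
#'   dimnames, or a long data frame with columns \code{snp_a, snp_b, r2}
#'   (see [read_ld_table()]). Absent pairs count as r-squared 0.
#' @param r2_max Maximum allowed r-squared between retained SNPs
#'   within the window (default 0.001).
#' @param window_kb Clump window in kb (default 10000).
#' @return The retained rows in p-value order, with an attribute
#'   \code{"removed"} naming each clumped-away SNP and its index SNP.
#' @export
clump <- function(candidates, ld, r2_max = 0.001, window_kb = 10000) {
  if (!nrow(candidates)) return(candidates)
  ord <- order(candidates$pval, candidates$snp_id)
  cand <- candidates[ord, , drop = FALSE]
  active <- rep(TRUE, nrow(cand))
  kept <- logical(nrow(cand))
  removed <- data.frame(snp_id = character(0), index_snp = character(0),
                        r2 = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cand))) {
    if (!active[i]) next
    kept[i] <- TRUE
    active[i] <- FALSE
    j <- which(active)
    if (!length(j)) next
    same_chr <- cand$chrom[j] == cand$chrom[i]
    close_by <- abs(cand$pos[j] - cand$pos[i]) <= window_kb * 1000
    cand_j <- j[same_chr & close_by]
    if (!length(cand_j)) next
    r2 <- vapply(cand$snp_id[cand_j],
                 function(s) ld_r2(ld, cand$snp_id[i], s), numeric(1))
    drop <- cand_j[r2 > r2_max]
    if (length(drop)) {
      removed <- rbind(removed, data.frame(
        snp_id = cand$snp_id[drop], index_snp = cand$snp_id[i],
        r2 = r2[r2 > r2_max], stringsAsFactors = FALSE))
      active[drop] <- FALSE
    }
  }
  out <- cand[kept, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  attr(out, "trait_label") <- attr(candidates, "trait_label")
  class(out) <- class(candidates)
  out
}

#' Read a long-format LD table (snp_a, snp_b, r2)
#'
#' @param path TSV with header \code{snp_a snp_b r2}.
#' @return A data frame usable as the \code{ld} argument of [clump()].
#' @export
read_ld_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("snp_a", "snp_b", "r2")
  if (!all(need %in% names(tab)))
    stop("LD table must have columns snp_a, snp_b, r2", call. = FALSE)
  tab
}

#' Per-SNP and mean instrument-strength F statistics
#'
#' Uses the square of the Wald z, \code{F_j = (beta_j / se_j)^2}. By the
#' usual weak-instrument convention the instrument set is flagged weak when
#' the mean F falls below \code{f_min} (default 10); per-SNP F values are
#' also returned so callers can instead drop individual weak SNPs.
#'
#' @param instruments A \code{sumstats} table.
#' @param f_min Weak-instrument threshold on the mean F.
#' @return A list: \code{per_snp} (data frame snp_id/f/weak), \code{mean_f},
#'   \code{weak_flag} (mean F < f_min), \code{weak_snps}.
#' @export
f_statistics <- function(instruments, f_min = 10) {
  f <- (instruments$beta / instruments$se)^2
  per_snp <- data.frame(snp_id = instruments$snp_id, f = f,
                        weak = f < f_min, stringsAsFactors = FALSE)
  list(per_snp = per_snp,
       mean_f = mean(f),
       weak_flag = mean(f) < f_min,
       weak_snps = per_snp$snp_id[per_snp$weak])
}

#' Exclude instruments associated with known confounders
#'
#' Removes SNPs that a local annotation table (standing in for a
#' PhenoScanner query) links to any listed confounder trait at
#' \code{pval < p_threshold}.
#'
#' @param instruments A \code{sumstats} table.
#' @param annotations Data frame with columns \code{snp_id, trait, pval}.
#' @param p_threshold Association threshold (default 1e-5).
#' @param confounder_traits Character vector of trait names to screen
#'   against; \code{NULL} (default) treats every trait in
#'   \code{annotations} as a confounder.
#' @return Filtered table with attribute \code{"removed"} (snp_id, trait,
#'   pval of each exclusion).
#' @export
confounder_filter <- function(instruments, annotations, p_threshold = 1e-5,
                              confounder_traits = NULL) {
  if (is.null(annotations) || !nrow(annotations)) {
    attr(instruments, "removed") <-
      data.frame(snp_id = character(0), trait = character(0),
                 pval = numeric(0), stringsAsFactors = FALSE)
    return(instruments)
  }
  ann <- annotations
  if (!is.null(confounder_traits))
    ann <- ann[ann$trait %in% confounder_traits, , drop = FALSE]
  hits <- ann[ann$pval < p_threshold & ann$snp_id %in% instruments$snp_id, ,
              drop = FALSE]
  out <- instruments[!(instruments$snp_id %in% hits$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- hits[, c("snp_id", "trait", "pval")]
  attr(out, "trait_label") <- attr(instruments, "trait_label")
  class(out) <- class(instruments)
  out
}

#' Full instrument-selection cascade for one exposure
#'
#' Applies, in order: the significance threshold, greedy LD clumping,
#' confounder exclusion, and F-statistic assessment, recording each
#' filter's removals.
#'
#' @param stats Exposure \code{sumstats}.
#' @param ld Optional LD lookup for [clump()]; \code{NULL} skips clumping.
#' @param annotations Optional confounder annotation table.
#' @param p_threshold,r2_max,window_kb,confounder_p,confounder_traits,f_min
#'   Thresholds as in the individual filters.
#' @return A list of class \code{"instrument_set"}: \code{instruments}
#'   (the surviving \code{sumstats} rows), \code{f} (the [f_statistics()]
#'   result), and \code{audit}, a per-stage data frame of candidate counts
#'   satisfying removed + retained = candidates at every stage.
#' @export
select_instruments <- function(stats, ld = NULL, annotations = NULL,
                               p_threshold = 5e-8, r2_max = 0.001,
                               window_kb = 10000, confounder_p = 1e-5,
                               confounder_traits = NULL, f_min = 10) {
  audit <- data.frame(stage = character(0), candidates = integer(0),
                      removed = integer(0), retained = integer(0),
                      stringsAsFactors = FALSE)
  note <- function(stage, before, after)
    rbind(audit, data.frame(stage = stage, candidates = before,
                            removed = before - after, retained = after,
                            stringsAsFactors = FALSE))

  n0 <- nrow(stats)
  sig <- suppressWarnings(significance_filter(stats, p_threshold))
  audit <- note("significance", n0, nrow(sig))

  if (!is.null(ld) && nrow(sig)) {
    clumped <- clump(sig, ld, r2_max = r2_max, window_kb = window_kb)
  } else clumped <- sig
  audit <- note("clump", nrow(sig), nrow(clumped))

  conf <- confounder_filter(clumped, annotations, p_threshold = confounder_p,
                            confounder_traits = confounder_traits)
  audit <- note("confounder", nrow(clumped), nrow(conf))

  fstat <- if (nrow(conf)) f_statistics(conf, f_min = f_min) else
    list(per_snp = NULL, mean_f = NA_real_, weak_flag = NA, weak_snps = character(0))

  structure(list(instruments = conf, f = fstat, audit = audit,
                 clump_removed = attr(clumped, "removed"),
                 confounder_removed = attr(conf, "removed")),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument selection\n")
  print(x$audit, row.names = FALSE)
  if (!is.null(x$f$per_snp))
    cat(sprintf("  mean F = %.1f%s\n", x$f$mean_f,
                if (isTRUE(x$f$weak_flag)) " [WEAK: mean F < threshold]" else ""))
  invisible(x)
}
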