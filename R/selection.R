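# LC-based candidate selection and the paired leaf/phloem comparison.
# Selection is a strict LC > threshold rule (default 30); the LC
# distribution per tissue is characterised descriptively (10-unit histogram,
# Shapiro-Wilk) but never gates the pipeline.

#' Select candidate records by local coverage
#'
#' Strict rule: a record is selected iff `lc > threshold`. Idempotent and
#' order-independent.
#'
#' @param records Candidate-record tibble (must carry an `lc` column).
#' @param threshold Strict LC threshold (default 30).
#' @return The selected subset, with `selected` set to TRUE.
#' @export
filter_by_lc <- function(records, threshold = 30) {
  if (!"lc" %in% names(records)) abort_input("records must carry an lc column")
  if (any(is.na(records$lc))) abort_input("lc must be present on every record")
  out <- records[records$lc > threshold, , drop = FALSE]
  out$selected <- rep(TRUE, nrow(out))
  out
}

#' Histogram of LC values in fixed-width bins
#'
#' Bins are `[0, w), [w, 2w), ...` up to the largest value; counts conserve
#' the total.
#'
#' @param lc_values Non-negative LC values.
#' @param bin_width Bin width in LC units (default 10).
#' @return Tibble with `bin_start`, `bin_end`, `count` (empty for empty
#'   input).
#' @export
lc_histogram <- function(lc_values, bin_width = 10) {
  if (bin_width <= 0) abort_config("bin_width must be positive")
  if (length(lc_values) == 0) {
    return(tibble(bin_start = numeric(), bin_end = numeric(),
                  count = integer()))
  }
  if (any(lc_values < 0)) abort_input("LC values must be non-negative")
  bin <- floor(lc_values / bin_width)
  nbin <- max(bin) + 1
  counts <- tabulate(bin + 1L, nbin)
  tibble(bin_start = (seq_len(nbin) - 1) * bin_width,
         bin_end = seq_len(nbin) * bin_width,
         count = counts)
}

#' Shapiro-Wilk normality test
#'
#' Wraps the standard Royston implementation (`stats::shapiro.test`). Used
#' descriptively on LC distributions, which in practice are strongly
#' right-skewed.
#'
#' @param values Numeric sample, 3 <= n <= 5000, non-degenerate.
#' @return A list with `W` and `p_value`.
#' @export
normality_test <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) abort_stats("Shapiro-Wilk requires 3 <= n <= 5000")
  if (length(unique(values)) == 1) {
    abort_stats("all values are identical; the test statistic is undefined")
  }
  res <- shapiro.test(values)
  list(W = unname(res$statistic), p_value = res$p.value)
}

#' LC distribution summary for one tissue
#'
#' Bundles the raw LC values, the fixed-width histogram, and the
#' Shapiro-Wilk statistic into one object with [tidy()]/[glance()]/
#' [autoplot()] methods. When the test is undefined (n < 3 or degenerate),
#' `W` and `p_value` are NA.
#'
#' @param lc_values Non-negative LC values.
#' @param tissue Tissue label.
#' @param bin_width Histogram bin width (default 10).
#' @return An `lc_distribution` object.
#' @export
lc_distribution <- function(lc_values, tissue = NA_character_, bin_width = 10) {
  sw <- tryCatch(normality_test(lc_values),
                 phloemir_stats_error = function(e) list(W = NA_real_,
                                                         p_value = NA_real_))
  structure(list(tissue = tissue, lc_values = lc_values,
                 bin_width = bin_width,
                 histogram = lc_histogram(lc_values, bin_width),
                 W = sw$W, p_value = sw$p_value),
            class = "lc_distribution")
}

#' @export
print.lc_distribution <- function(x, ...) {
  cat(sprintf("<lc_distribution> %s: n = %d, W = %s, p = %s\n",
              x$tissue, length(x$lc_values),
              format(x$W, digits = 5), format(x$p_value, digits = 4)))
  invisible(x)
}

#' @rdname lc_distribution
#' @param x An `lc_distribution` object.
#' @param ... Unused.
#' @export
tidy.lc_distribution <- function(x, ...) {
  mutate(x$histogram, tissue = x$tissue, .before = 1)
}

#' @rdname lc_distribution
#' @export
glance.lc_distribution <- function(x, ...) {
  tibble(tissue = x$tissue, n = length(x$lc_values),
         W = x$W, p_value = x$p_value, bin_width = x$bin_width)
}

#' Compare LC-selected candidates between two tissues
#'
#' Reduces each tissue to at most one record per query (lowest E-value,
#' ties broken by highest LC), joins the tissues by query, and assigns a
#' mobility class per query: `shared` if selected in both tissues,
#' `phloem_specific` / `leaf_specific` if selected in exactly one,
#' `neither` otherwise. A query absent from a tissue's records is a
#' "no match" in that tissue.
#'
#' @param leaf_records,phloem_records Candidate-record tibbles for the two
#'   tissues.
#' @param threshold Strict LC selection threshold (default 30).
#' @param reduce If FALSE, duplicate (tissue, query) keys raise an input
#'   error instead of being reduced.
#' @return A `tissue_comparison` tibble: one row per query with per-tissue
#'   contig, length, AC, LC, E-value, selection flags and `class`. Summary
#'   counts are available via [glance()].
#' @export
compare_tissues <- function(leaf_records, phloem_records, threshold = 30,
                            reduce = TRUE) {
  reduce_one <- function(rec) {
    if (nrow(rec) == 0) return(rec)
    dup <- anyDuplicated(rec$query_id) > 0
    if (dup && !reduce) {
      abort_input("duplicate (tissue, query) keys; set reduce = TRUE")
    }
    rec |>
      arrange(.data$query_id, .data$evalue, desc(.data$lc)) |>
      group_by(.data$query_id) |>
      slice(1) |>
      ungroup()
  }
  leaf <- reduce_one(leaf_records)
  phloem <- reduce_one(phloem_records)
  keep <- c("query_id", "contig_id", "contig_len", "similarity_len",
            "evalue", "ac", "lc")
  lhs <- leaf[, intersect(keep, names(leaf)), drop = FALSE]
  rhs <- phloem[, intersect(keep, names(phloem)), drop = FALSE]
  names(lhs)[-1] <- paste0("leaf_", names(lhs)[-1])
  names(rhs)[-1] <- paste0("phloem_", names(rhs)[-1])
  cmp <- full_join(lhs, rhs, by = "query_id") |> arrange(.data$query_id)
  cmp$leaf_selected <- !is.na(cmp$leaf_lc) & cmp$leaf_lc > threshold
  cmp$phloem_selected <- !is.na(cmp$phloem_lc) & cmp$phloem_lc > threshold
  cmp$class <- dplyr::case_when(
    cmp$leaf_selected & cmp$phloem_selected ~ "shared",
    cmp$phloem_selected ~ "phloem_specific",
    cmp$leaf_selected ~ "leaf_specific",
    TRUE ~ "neither")
  out <- structure(cmp, class = c("tissue_comparison", class(cmp)))
  attr(out, "lc_threshold") <- threshold
  out
}

#' @rdname compare_tissues
#' @param x A `tissue_comparison`.
#' @param ... Unused.
#' @export
glance.tissue_comparison <- function(x, ...) {
  tibble(n_queries = nrow(x),
         n_leaf_selected = sum(x$leaf_selected),
         n_phloem_selected = sum(x$phloem_selected),
         n_shared = sum(x$class == "shared"),
         n_phloem_specific = sum(x$class == "phloem_specific"),
         n_leaf_specific = sum(x$class == "leaf_specific"),
         n_neither = sum(x$class == "neither"),
         lc_threshold = attr(x, "lc_threshold"))
}

#' @rdname compare_tissues
#' @export
tidy.tissue_comparison <- function(x, ...) {
  as_tibble(x)
}

#' Read the packaged paired-tissue abundance table
#'
#' Loads the packaged fixture transcribed from the published paired
#' leaf/phloem pre-miRNA abundance table (contig name, length, AC, LC per
#' tissue plus per-query alignment length and E-value; "no match" cells are
#' NA).
#'
#' @param path Path to a tab-separated table; default the packaged fixture.
#' @return A tibble with one row per pre-miRNA.
#' @export
read_table1 <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1.tsv", package = "phloemir",
                        mustWork = TRUE)
  }
  readr::read_tsv(path, show_col_types = FALSE, na = "NA")
}

#' Tissue comparison directly from a paired abundance table
#'
#' Converts a table in the packaged fixture's layout into per-tissue
#' candidate records (rows present in a tissue only when that tissue has a
#' matching contig) and runs [compare_tissues()]. The table's rows are
#' assumed already homology-screened, so only the LC rule is applied.
#'
#' @param table A tibble from [read_table1()], or NULL for the packaged
#'   fixture.
#' @param threshold Strict LC threshold (default 30).
#' @return A `tissue_comparison`.
#' @export
compare_from_table <- function(table = NULL, threshold = 30) {
  if (is.null(table)) table <- read_table1()
  recs <- function(prefix, tissue) {
    has <- !is.na(table[[paste0(prefix, "_contig")]])
    tibble(tissue = tissue,
           query_id = table$pre_mirna[has],
           contig_id = table[[paste0(prefix, "_contig")]][has],
           contig_len = table[[paste0(prefix, "_len")]][has],
           similarity_len = table$similarity_len[has],
           evalue = table$evalue[has],
           ac = table[[paste0(prefix, "_ac")]][has],
           lc = table[[paste0(prefix, "_lc")]][has])
  }
  compare_tissues(recs("leaf", "leaf"), recs("phloem", "phloem"),
                  threshold = threshold)
}
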