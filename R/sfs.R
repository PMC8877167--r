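# Site-frequency-spectrum containers, folding, hypergeometric
# splitting, pN/pS, weighted SFS averaging, and dofe-format I/O.

#' Construct a site frequency spectrum
#'
#' @param counts nonnegative counts of segregating sites by derived
#'   allele class: length `n - 1` (classes `1..n-1`) when unfolded, or
#'   `floor(n / 2)` when folded.
#' @param n haploid sample size (number of chromosomes sampled).
#' @param L number of surveyed sites, including invariant ones. Defaults
#'   to the number of segregating sites when only variable positions are
#'   known; supply the true value whenever available.
#' @param folded logical; minor-allele (folded) spectrum or
#'   derived-allele (unfolded) spectrum.
#' @return Object of class `sfs_spectrum`.
#' @export
sfs_spectrum <- function(counts, n, L = sum(counts), folded = FALSE) {
  .check_number(n, "n", positive = TRUE)
  n <- as.integer(n)
  if (n < 2L) .stopf("n must be at least 2")
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0))
    .stopf("counts must be finite nonnegative numbers")
  expect_len <- if (folded) n %/% 2L else n - 1L
  if (length(counts) != expect_len)
    .stopf("counts must have length %d for n = %d (%s)", expect_len, n,
           if (folded) "folded" else "unfolded")
  .check_number(L, "L", nonneg = TRUE)
  structure(list(counts = as.numeric(counts), n = n, L = as.numeric(L),
                 folded = isTRUE(folded)),
            class = "sfs_spectrum")
}

#' @export
print.sfs_spectrum <- function(x, ...) {
  cat(sprintf("<%s SFS: n = %d, L = %g, %g segregating sites>\n",
              if (x$folded) "folded" else "unfolded", x$n, x$L,
              sum(x$counts)))
  invisible(x)
}

#' Fold an unfolded spectrum
#'
#' Merges derived-allele class `i` with class `n - i`; for even `n` the
#' middle class is left unmerged. Sample size and site count are
#' preserved.
#'
#' @param sfs an unfolded [sfs_spectrum()].
#' @export
fold_sfs <- function(sfs) {
  stopifnot(inherits(sfs, "sfs_spectrum"))
  if (sfs$folded) .stopf("spectrum is already folded")
  n <- sfs$n
  half <- n %/% 2L
  folded <- vapply(seq_len(half), function(i) {
    j <- n - i
    if (j == i) sfs$counts[i] else sfs$counts[i] + sfs$counts[j]
  }, numeric(1))
  sfs_spectrum(folded, n = n, L = sfs$L, folded = TRUE)
}

#' Split a spectrum into two independent halves
#'
#' Each site is assigned to one of two sets with probability 1/2,
#' independently (a binomial(count, 1/2) draw per frequency class).
#' Conditional on the class total this is exactly the hypergeometric
#' partition, and yields two independent spectra: one can be used to
#' estimate pN/pS and the other to fit rates, removing the sampling
#' non-independence between the two statistics.
#'
#' @param sfs an [sfs_spectrum()] with integer counts.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return List of two `sfs_spectrum` objects summing class-wise to the
#'   input.
#' @export
split_sfs <- function(sfs, seed) {
  stopifnot(inherits(sfs, "sfs_spectrum"))
  if (any(sfs$counts != round(sfs$counts)))
    .stopf("split_sfs requires integer counts")
  with_seed(seed, {
    first <- stats::rbinom(length(sfs$counts), size = as.integer(sfs$counts),
                           prob = 0.5)
    L1 <- if (sfs$L == round(sfs$L))
      stats::rbinom(1L, size = as.integer(sfs$L), prob = 0.5) else sfs$L / 2
    list(sfs_spectrum(first, n = sfs$n, L = L1, folded = sfs$folded),
         sfs_spectrum(sfs$counts - first, n = sfs$n, L = sfs$L - L1,
                      folded = sfs$folded))
  })
}

#' Weighted average of spectra
#'
#' Class-wise weighted average of spectra sharing the same sample size
#' and folded status, with weights normalized to sum to one; `L` is
#' averaged with the same weights. Used to build the four-fold
#' synonymous comparator for amino-acid pairs reachable through more
#' than one mutational type, weighting each type's spectrum by the
#' genomic frequency of the relevant codons.
#'
#' @param spectra list of [sfs_spectrum()] objects.
#' @param weights nonnegative weights, at least one positive.
#' @export
weighted_average_sfs <- function(spectra, weights) {
  if (!length(spectra)) .stopf("no spectra supplied")
  stopifnot(all(vapply(spectra, inherits, TRUE, "sfs_spectrum")))
  if (length(weights) != length(spectra))
    .stopf("need one weight per spectrum")
  if (any(weights < 0) || !any(weights > 0))
    .stopf("weights must be nonnegative with at least one positive")
  n <- spectra[[1]]$n; folded <- spectra[[1]]$folded
  for (s in spectra)
    if (s$n != n || s$folded != folded)
      .stopf("all spectra must share n and folded status")
  w <- weights / sum(weights)
  counts <- Reduce(`+`, Map(function(s, wi) wi * s$counts, spectra, w))
  L <- sum(vapply(spectra, `[[`, 0, "L") * w)
  sfs_spectrum(counts, n = n, L = L, folded = folded)
}

#' Polymorphism counts
#'
#' @param p_n,p_s nonsynonymous and synonymous polymorphism counts.
#' @param l_n,l_s corresponding site counts (needed for per-site
#'   ratios).
#' @export
poly_counts <- function(p_n, p_s, l_n = NA_real_, l_s = NA_real_) {
  .check_number(p_n, "p_n", nonneg = TRUE)
  .check_number(p_s, "p_s", nonneg = TRUE)
  structure(list(p_n = p_n, p_s = p_s, l_n = l_n, l_s = l_s),
            class = "poly_counts")
}

#' Divergence counts
#'
#' @param d_sel,d_neu substitution counts at selected and neutral sites.
#' @param l_sel,l_neu numbers of selected and neutral sites over which
#'   divergence was counted.
#' @export
div_counts <- function(d_sel, d_neu, l_sel, l_neu) {
  .check_number(d_sel, "d_sel", nonneg = TRUE)
  .check_number(d_neu, "d_neu", nonneg = TRUE)
  .check_number(l_sel, "l_sel", nonneg = TRUE)
  .check_number(l_neu, "l_neu", nonneg = TRUE)
  structure(list(d_sel = d_sel, d_neu = d_neu,
                 l_sel = l_sel, l_neu = l_neu),
            class = "div_counts")
}

#' pN/pS ratio
#'
#' @param poly a [poly_counts()] object.
#' @param per_site if `TRUE`, normalize each count by its site count
#'   before taking the ratio.
#' @export
pnps <- function(poly, per_site = FALSE) {
  stopifnot(inherits(poly, "poly_counts"))
  if (poly$p_s == 0) .stopf("pN/pS undefined: p_s is zero")
  if (per_site) {
    if (!is.finite(poly$l_n) || !is.finite(poly$l_s) ||
        poly$l_n <= 0 || poly$l_s <= 0)
      .stopf("per-site pN/pS requires positive l_n and l_s")
    (poly$p_n / poly$l_n) / (poly$p_s / poly$l_s)
  } else poly$p_n / poly$p_s
}

# ---- dofe format ----------------------------------------------------
# Layout (tab-separated), one record per line after the header:
#   name  n  L_sel  <n-1 selected counts>  L_neu  <n-1 neutral counts>
#   L_sel_div  D_sel  L_neu_div  D_neu
# An optional "#unfolded" line after the header marks unfolded spectra.

#' Read a dofe file
#'
#' Parses the tabular dofe layout used by MK-style DFE estimators:
#' a free-text header line, an optional `#unfolded` marker, then one
#' record per line pairing a selected and a neutral SFS with divergence
#' counts. Only the 10-field-per-record dialect described above is
#' accepted; anything else is rejected with the offending line number.
#'
#' @param path file path.
#' @return List of records, each a list with `name`, `sel` and `neu`
#'   ([sfs_spectrum()]s) and `div` ([div_counts()]).
#' @export
read_dofe <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  if (!length(lines)) .stopf("empty dofe file: %s", path)
  body_start <- 2L
  unfolded <- FALSE
  if (length(lines) >= 2L && grepl("^#unfolded", lines[2L])) {
    unfolded <- TRUE
    body_start <- 3L
  }
  recs <- list()
  for (ln in seq(body_start, length.out = max(0L, length(lines) - body_start + 1L))) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L) .stopf("dofe line %d: too few fields", ln)
    name <- f[1]
    n <- suppressWarnings(as.integer(f[2]))
    if (is.na(n) || n < 2L) .stopf("dofe line %d: bad sample size '%s'", ln, f[2])
    expect <- 2L + 1L + (n - 1L) + 1L + (n - 1L) + 4L
    if (length(f) != expect)
      .stopf("dofe line %d: expected %d fields for n = %d, found %d",
             ln, expect, n, length(f))
    num <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(num)) .stopf("dofe line %d: non-numeric field", ln)
    num <- num[-1]  # drop n
    L_sel <- num[1]; sel <- num[2:n]
    L_neu <- num[n + 1]; neu <- num[(n + 2):(2 * n)]
    tail4 <- num[(2 * n + 1):(2 * n + 4)]
    recs[[length(recs) + 1L]] <- list(
      name = name,
      sel = sfs_spectrum(sel, n = n, L = L_sel, folded = !unfolded),
      neu = sfs_spectrum(neu, n = n, L = L_neu, folded = !unfolded),
      div = div_counts(d_sel = tail4[2], d_neu = tail4[4],
                       l_sel = tail4[1], l_neu = tail4[3]))
  }
  recs
}

#' Write a dofe file
#'
#' Output is bit-stable (fixed field order, tab separators, newline at
#' end of file) so golden-file comparisons are exact.
#'
#' @param records list of records as returned by [read_dofe()].
#' @param path output file path.
#' @param unfolded logical; write the `#unfolded` marker. Records whose
#'   spectra are folded cannot be written as unfolded.
#' @param header first line of the file.
#' @export
write_dofe <- function(records, path, unfolded = TRUE,
                       header = "mkshift dofe export") {
  fmt_num <- function(x) formatC(x, format = "fg", digits = 15)
  lines <- c(header, if (unfolded) "#unfolded")
  for (r in records) {
    if (!all(c("name", "sel", "neu", "div") %in% names(r)))
      .stopf("each record needs fields name, sel, neu, div")
    if (unfolded && (r$sel$folded || r$neu$folded))
      .stopf("record '%s' holds folded spectra; cannot write as unfolded",
             r$name)
    n <- r$sel$n
    if (r$neu$n != n) .stopf("record '%s': sample sizes differ", r$name)
    lines <- c(lines, paste(c(
      r$name, n,
      fmt_num(r$sel$L), fmt_num(r$sel$counts),
      fmt_num(r$neu$L), fmt_num(r$neu$counts),
      fmt_num(r$div$l_sel), fmt_num(r$div$d_sel),
      fmt_num(r$div$l_neu), fmt_num(r$div$d_neu)), collapse = "\t"))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
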