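# Standard-genetic-code utilities: single-step amino-acid pairs,
# mutational-type classification (including BGC-neutral status),
# four-fold degenerate step catalogues, and physico-chemical
# dissimilarity between amino acids.

.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

.BASES <- c("A", "C", "G", "T")

#' Translate codons under the standard genetic code
#'
#' @param codon character vector of 3-letter nucleotide strings over
#'   `A`, `C`, `G`, `T`.
#' @return Character vector of single-letter amino-acid codes, with `"*"`
#'   marking stop codons.
#' @examples
#' translate_codon(c("GCA", "ATG", "TGA"))
#' @export
translate_codon <- function(codon) {
  if (!is.character(codon) || any(nchar(codon) != 3L))
    .stopf("codons must be 3-letter character strings")
  codon <- toupper(codon)
  if (!all(strsplit(paste(codon, collapse = ""), "")[[1]] %in% .BASES))
    .stopf("codons may only contain A, C, G, T")
  unname(.codon_table()[codon])
}

#' Classify a nucleotide change by mutational type
#'
#' The six unordered nucleotide pairs define six mutational types. The
#' types `A:T` and `C:G` leave GC content unchanged and are therefore
#' unaffected by GC-biased gene conversion ("BGC-neutral"); restricting
#' an analysis to these changes removes BGC as a confounder.
#'
#' @param base_a,base_b distinct nucleotides.
#' @return An object of class `mutational_type` with fields `bases`
#'   (sorted pair), `label` (e.g. `"A:T"`) and `bgc_neutral`.
#' @examples
#' classify_mutation("A", "T")$bgc_neutral
#' @export
classify_mutation <- function(base_a, base_b) {
  base_a <- toupper(base_a); base_b <- toupper(base_b)
  if (!base_a %in% .BASES || !base_b %in% .BASES)
    .stopf("bases must be one of A, C, G, T")
  if (base_a == base_b) .stopf("bases must differ")
  bases <- sort(c(base_a, base_b))
  label <- paste(bases, collapse = ":")
  structure(list(bases = bases, label = label,
                 bgc_neutral = label %in% c("A:T", "C:G")),
            class = "mutational_type")
}

#' @export
print.mutational_type <- function(x, ...) {
  cat(sprintf("<mutational type %s%s>\n", x$label,
              if (x$bgc_neutral) ", BGC-neutral" else ""))
  invisible(x)
}

# canonical label for vectors of base pairs (internal fast path)
.type_label <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = ":"), paste(b, a, sep = ":"))
}

.BGC_NEUTRAL_TYPES <- c("A:T", "C:G")

#' All six mutational type labels
#' @return Character vector of the six unordered nucleotide pair labels.
#' @export
mutational_types <- function() {
  cmb <- utils::combn(.BASES, 2)
  paste(cmb[1, ], cmb[2, ], sep = ":")
}

# Enumerate all unordered single-nucleotide codon changes, annotated.
# Columns: codon_a, codon_b (codon_a < codon_b), pos (1..3), type,
# bgc_neutral, aa_a, aa_b.
.all_codon_steps <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- .codon_table()
    codons <- names(gc)
    rows <- list()
    for (c1 in codons) for (pos in 1:3) for (b in .BASES) {
      c2 <- c1
      substr(c2, pos, pos) <- b
      if (c2 <= c1) next
      rows[[length(rows) + 1L]] <- data.frame(
        codon_a = c1, codon_b = c2, pos = pos,
        type = .type_label(substr(c1, pos, pos), substr(c2, pos, pos)),
        aa_a = unname(gc[[c1]]), aa_b = unname(gc[[c2]]),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out$bgc_neutral <- out$type %in% .BGC_NEUTRAL_TYPES
    cache <<- out
    out
  }
})

#' Enumerate amino-acid pairs separated by a single mutational step
#'
#' Scans all single-nucleotide codon changes under the standard genetic
#' code and collects the unordered pairs of distinct amino acids they
#' connect; stop codons are excluded as both end points. Under the
#' standard code there are exactly 75 such pairs.
#'
#' @param bgc_neutral_only if `TRUE`, only steps whose mutational type is
#'   `A:T` or `C:G` are retained (the changes unaffected by GC-biased
#'   gene conversion), and pairs left with no steps are dropped. Pairs
#'   are filtered by their steps, not wholesale: a pair is kept as long
#'   as at least one BGC-neutral step connects it.
#' @return Named list of `aa_pair` objects. Each has `aa` (two sorted
#'   single-letter codes) and `steps`, a data frame of the codon changes
#'   realizing the pair (`codon_a` translates to `aa[1]`).
#' @examples
#' length(single_step_pairs())  # 75
#' single_step_pairs()[["A:G"]]$steps
#' @export
single_step_pairs <- function(bgc_neutral_only = FALSE) {
  steps <- .all_codon_steps()
  ns <- steps[steps$aa_a != "*" & steps$aa_b != "*" & steps$aa_a != steps$aa_b, ]
  if (bgc_neutral_only) ns <- ns[ns$bgc_neutral, ]
  if (nrow(ns) == 0L) return(structure(list(), names = character()))
  # orient each step so codon_a translates to the alphabetically first aa
  flip <- ns$aa_a > ns$aa_b
  tmp <- ns$codon_a[flip]; ns$codon_a[flip] <- ns$codon_b[flip]; ns$codon_b[flip] <- tmp
  tmp <- ns$aa_a[flip]; ns$aa_a[flip] <- ns$aa_b[flip]; ns$aa_b[flip] <- tmp
  key <- paste(ns$aa_a, ns$aa_b, sep = ":")
  out <- lapply(split(ns, key), function(d) {
    structure(list(
      aa = c(d$aa_a[1L], d$aa_b[1L]),
      steps = d[order(d$codon_a, d$codon_b),
                c("codon_a", "codon_b", "pos", "type", "bgc_neutral")]),
      class = "aa_pair")
  })
  out[order(names(out))]
}

#' @export
print.aa_pair <- function(x, ...) {
  cat(sprintf("<amino-acid pair %s-%s: %d single-nucleotide step(s), types %s>\n",
              x$aa[1], x$aa[2], nrow(x$steps),
              paste(unique(x$steps$type), collapse = ", ")))
  invisible(x)
}

#' Third-position steps within four-fold degenerate codon families
#'
#' Four-fold degenerate families (third positions where all four
#' nucleotides encode the same amino acid) provide the synonymous
#' comparator for each mutational type: a selected amino-acid change of
#' type `C:G`, say, is compared with synonymous `C:G` changes at
#' four-fold sites.
#'
#' @return Named list over the six mutational type labels; each element
#'   is a data frame of `(codon_a, codon_b)` third-position synonymous
#'   steps (`codon_a < codon_b`) within four-fold families.
#' @examples
#' fourfold_steps_by_type()[["C:G"]]
#' @export
fourfold_steps_by_type <- function() {
  gc <- .codon_table()
  codons <- names(gc)
  fam <- split(codons, paste0(substr(codons, 1, 2), gc))
  four <- Filter(function(x) length(x) == 4L, fam)
  rows <- list()
  for (f in four) {
    cmb <- utils::combn(sort(f), 2)
    for (j in seq_len(ncol(cmb))) {
      c1 <- cmb[1, j]; c2 <- cmb[2, j]
      rows[[length(rows) + 1L]] <- data.frame(
        codon_a = c1, codon_b = c2,
        type = .type_label(substr(c1, 3, 3), substr(c2, 3, 3)),
        stringsAsFactors = FALSE)
    }
  }
  all <- do.call(rbind, rows)
  out <- lapply(mutational_types(), function(t) {
    d <- all[all$type == t, c("codon_a", "codon_b")]
    rownames(d) <- NULL
    d[order(d$codon_a, d$codon_b), , drop = FALSE]
  })
  names(out) <- mutational_types()
  out
}

#' Amino-acid volume and polarity scores
#'
#' Reads the packaged physico-chemical property table (Grantham's
#' polarity and volume scores, as tabulated in AAindex1). The table is
#' injectable wherever it is consumed so alternative scorings can be
#' supplied.
#'
#' @param file optional path to a TSV with columns
#'   `amino_acid`, `volume`, `polarity`; defaults to the packaged table.
#' @return Data frame with one row per amino acid.
#' @export
aa_properties <- function(file = NULL) {
  file <- file %||% system.file("extdata", "aa_properties_grantham.tsv",
                                package = "mkshift", mustWork = TRUE)
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("amino_acid", "volume", "polarity")
  if (!all(need %in% names(tab))) .stopf("property table must have columns %s",
                                         paste(need, collapse = ", "))
  if (nrow(tab) != 20L || anyDuplicated(tab$amino_acid))
    .stopf("property table must list each of the 20 amino acids once")
  if (!all(is.finite(tab$volume)) || !all(is.finite(tab$polarity)))
    .stopf("property scores must be finite")
  tab
}

#' Physico-chemical dissimilarity of an amino-acid pair
#'
#' @param pair an `aa_pair` (from [single_step_pairs()]) or a character
#'   vector of two amino-acid codes.
#' @param table property table as returned by [aa_properties()].
#' @return Named numeric vector `c(dvolume, dpolarity)` of absolute
#'   score differences.
#' @export
pair_dissimilarity <- function(pair, table = aa_properties()) {
  aa <- if (inherits(pair, "aa_pair")) pair$aa else as.character(pair)
  if (length(aa) != 2L) .stopf("pair must contain two amino acids")
  idx <- match(aa, table$amino_acid)
  if (anyNA(idx)) .stopf("amino acid(s) %s missing from property table",
                         paste(aa[is.na(idx)], collapse = ", "))
  c(dvolume = abs(diff(table$volume[idx])),
    dpolarity = abs(diff(table$polarity[idx])))
}
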