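test_that("codon translation follows the standard code and validates input", {
  expect_equal(translate_codon(c("GCA", "ATG", "TGA")), c("A", "M", "*"))
  expect_equal(translate_codon("gca"), "A")
  expect_error(translate_codon("GXA"), "A, C, G, T")
  expect_error(translate_codon("GC"), "3-letter")
})

test_that("mutational types: six classes, BGC-neutral iff A:T or C:G", {
  expect_length(mutational_types(), 6L)
  expect_true(classify_mutation("A", "T")$bgc_neutral)
  expect_true(classify_mutation("G", "C")$bgc_neutral)
  expect_false(classify_mutation("C", "T")$bgc_neutral)
  bgc <- vapply(mutational_types(), function(t) {
    b <- strsplit(t, ":")[[1]]
    classify_mutation(b[1], b[2])$bgc_neutral
  }, logical(1))
  expect_equal(sum(bgc), 2L)
  expect_equal(classify_mutation("A", "G")$label,
               classify_mutation("G", "A")$label)
  expect_error(classify_mutation("A", "A"), "differ")
})

test_that("exactly 75 single-step pairs, internally consistent", {
  pairs <- single_step_pairs()
  expect_length(pairs, 75L)
  expect_false(anyDuplicated(names(pairs)) > 0)
  expect_true("A:G" %in% names(pairs))
  ag <- pairs[["A:G"]]$steps
  expect_true(any(ag$type == "C:G" & ag$pos == 2L))
  # Met-Trp differ at two codon positions, so they are not a pair
  expect_false("M:W" %in% names(pairs))
  for (p in pairs) {
    expect_gt(nrow(p$steps), 0)
    expect_equal(sort(unique(c(translate_codon(p$steps$codon_a),
                               translate_codon(p$steps$codon_b)))),
                 sort(p$aa))
    expect_equal(translate_codon(p$steps$codon_a),
                 rep(p$aa[1], nrow(p$steps)))
    # each step changes exactly one position, at the recorded one
    diffs <- mapply(function(a, b) {
      which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    }, p$steps$codon_a, p$steps$codon_b, SIMPLIFY = FALSE)
    expect_true(all(lengths(diffs) == 1L))
    expect_equal(unname(unlist(diffs)), p$steps$pos)
  }
})

test_that("union of pair steps equals the brute-force step enumeration", {
  pairs <- single_step_pairs()
  got <- sort(unlist(lapply(pairs, function(p)
    paste(pmin(p$steps$codon_a, p$steps$codon_b),
          pmax(p$steps$codon_a, p$steps$codon_b)))))
  bf <- brute_force_nonsyn_steps()
  want <- sort(paste(bf$codon_1, bf$codon_2))
  expect_equal(unname(got), want)
  # pair set also matches brute force
  bf_pairs <- sort(unique(ifelse(bf$aa_1 < bf$aa_2,
                                 paste(bf$aa_1, bf$aa_2, sep = ":"),
                                 paste(bf$aa_2, bf$aa_1, sep = ":"))))
  expect_equal(names(pairs), bf_pairs)
})

test_that("BGC restriction filters steps, keeping pairs with a neutral step", {
  all_pairs <- single_step_pairs()
  bgc <- single_step_pairs(bgc_neutral_only = TRUE)
  expect_true(all(names(bgc) %in% names(all_pairs)))
  for (p in bgc) {
    expect_true(all(p$steps$bgc_neutral))
    expect_true(all(p$steps$type %in% c("A:T", "C:G")))
  }
  # brute-force count of pairs reachable via a BGC-neutral step
  bf <- brute_force_nonsyn_steps()
  neutral <- bf[paste(pmin(bf$base_1, bf$base_2),
                      pmax(bf$base_1, bf$base_2), sep = ":") %in%
                  c("A:T", "C:G"), ]
  want <- length(unique(ifelse(neutral$aa_1 < neutral$aa_2,
                               paste(neutral$aa_1, neutral$aa_2),
                               paste(neutral$aa_2, neutral$aa_1))))
  expect_length(bgc, want)
})

test_that("four-fold catalogue lists synonymous third-position steps only", {
  ff <- fourfold_steps_by_type()
  expect_setequal(names(ff), mutational_types())
  total <- 0L
  for (t in names(ff)) {
    d <- ff[[t]]
    expect_gt(nrow(d), 0)
    total <- total + nrow(d)
    expect_equal(translate_codon(d$codon_a), translate_codon(d$codon_b))
    expect_equal(substr(d$codon_a, 1, 2), substr(d$codon_b, 1, 2))
    types <- mapply(function(a, b) classify_mutation(
      substr(a, 3, 3), substr(b, 3, 3))$label, d$codon_a, d$codon_b)
    expect_true(all(types == t))
  }
  # brute force: 8 four-fold families x choose(4, 2) unordered steps
  gc <- Biostrings::GENETIC_CODE
  fams <- split(names(gc), paste0(substr(names(gc), 1, 2), gc))
  n_four <- sum(lengths(fams) == 4L)
  expect_equal(n_four, 8L)
  expect_equal(total, n_four * choose(4, 2))
  # Ile is 3-fold: ATT<->ATC must not appear
  expect_false(any(vapply(ff, function(d)
    any(d$codon_a == "ATC" & d$codon_b == "ATT"), logical(1))))
  expect_true(any(ff[["C:G"]]$codon_a == "GCC" & ff[["C:G"]]$codon_b == "GCG"))
})

test_that("dissimilarity is a symmetric table lookup", {
  tab <- aa_properties()
  expect_equal(nrow(tab), 20L)
  d1 <- pair_dissimilarity(c("A", "G"), tab)
  expect_equal(unname(d1["dvolume"]),
               abs(tab$volume[tab$amino_acid == "A"] -
                     tab$volume[tab$amino_acid == "G"]))
  expect_equal(d1, pair_dissimilarity(c("G", "A"), tab))
  expect_equal(unname(pair_dissimilarity(c("A", "A"), tab)), c(0, 0))
  expect_error(pair_dissimilarity(c("A", "B"), tab), "missing")
  # injectable table
  tab2 <- tab; tab2$volume <- tab2$volume * 2
  expect_equal(unname(pair_dissimilarity(c("A", "G"), tab2)["dvolume"]),
               2 * unname(d1["dvolume"]))
})
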