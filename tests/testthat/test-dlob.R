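test_that("the default montage lookup maps channels to their lobes", {
  tab <- lobe_table(default_montage())
  expect_length(tab, 14L)
  expect_equal(unname(tab[5]), "TL")    # T7
  expect_equal(unname(tab[8]), "OR")    # O2
  expect_equal(unname(tab[14]), "FR")   # AF4
  expect_equal(unname(tab),
               c("FL", "FL", "FL", "FL", "TL", "PL", "OL",
                 "OR", "PR", "TR", "FR", "FR", "FR", "FR"))
})

test_that("feature indices decode to channel pairs, with merged-space folding", {
  expect_equal(feature_index_to_channels(2, 14), c(1L, 2L))
  ## merged vector: index 198 folds to 2 in the max-distance space
  expect_equal(feature_index_to_channels(198, 14, "merged"), c(1L, 2L))
  expect_equal(feature_index_to_channels(196, 14), c(14L, 14L))
  expect_error(feature_index_to_channels(197, 14, "min_distance"),
               "out of range")
  expect_error(feature_index_to_channels(0, 14), "out of range")
  expect_error(feature_index_to_channels(393, 14, "merged"), "out of range")
  ## decode agrees with the encoder for every in-image index
  pairs <- soxfe:::pair_index_table(14)
  for (r in sample(nrow(pairs), 20)) {
    idx <- (pairs[r, 1] - 1) * 14 + (pairs[r, 2] - 1) + 1   # 1-based index
    expect_equal(feature_index_to_channels(idx, 14), unname(pairs[r, ]))
  }
})

test_that("DLob strings hold two symbols per selected feature", {
  m <- default_montage()
  s21 <- build_dlob_string(sample(196, 21), m, "min_distance")
  expect_length(s21, 42L)
  expect_true(all(s21 %in% c("FL", "FR", "OL", "OR", "PL", "PR", "TL", "TR")))
  ## single feature index 2 decodes to channels (1, 2) = AF3, F7 -> FL FL
  expect_equal(as.character(build_dlob_string(2, m)), c("FL", "FL"))
  expect_length(build_dlob_string(integer(0), m), 0L)
  ## merged indices use the same lobe map in both halves
  expect_equal(as.character(build_dlob_string(198, m, "merged")),
               c("FL", "FL"))
})

test_that("symbol histogram of the reference explainability string matches hand counts", {
  s <- reference_dlob_string_1()
  expect_length(s, 42L)
  h <- symbol_histogram(s)
  expect_equal(sum(h), 42L)
  expect_equal(unname(h["FR"]), 20L)
  expect_equal(unname(h[c("PL", "OR", "OL")]), c(5L, 5L, 5L))
  expect_equal(unname(h["FL"]), 3L)
  expect_equal(unname(h[c("TR", "PR")]), c(2L, 2L))
  expect_equal(unname(symbol_histogram(character(0))), rep(0L, 8))
  expect_error(symbol_histogram(c("FL", "ZZ")), "unknown DLob symbol")
})

test_that("Shannon entropy follows the frequency formula", {
  expect_equal(shannon_entropy(rep("FL", 10)), 0)
  expect_equal(shannon_entropy(c("FL", "FR")), 1)         # 1 bit
  expect_equal(shannon_entropy(c("FL", "FR", "FL", "FR"), base = exp(1)),
               log(2))
  ## hand-computed for the reference string's frequencies (20,5,5,5,3,2,2)/42
  p <- c(20, 5, 5, 5, 3, 2, 2) / 42
  expect_equal(shannon_entropy(reference_dlob_string_1()),
               -sum(p * log2(p)))
  expect_error(shannon_entropy(character(0)), "empty")
})

test_that("transition matrices count adjacent or within-feature pairs", {
  tm <- transition_matrix(c("FL", "FL", "FR"))
  expect_equal(tm["FL", "FL"], 1L)
  expect_equal(tm["FL", "FR"], 1L)
  expect_equal(sum(tm), 2L)

  s <- reference_dlob_string_1()
  cons <- transition_matrix(s, "consecutive")
  expect_equal(sum(cons), 41L)                     # length - 1
  pair <- transition_matrix(s, "per_feature_pair")
  expect_equal(sum(pair), 21L)                     # length / 2
  ## row sums = outgoing occurrences (last position excluded in consecutive)
  out_counts <- symbol_histogram(s[-length(s)])
  expect_equal(rowSums(cons)[names(out_counts)], as.numeric(out_counts),
               ignore_attr = TRUE)
  expect_error(transition_matrix("FL"), "at least 2")
  expect_error(transition_matrix(c("FL", "FR", "FL"), "per_feature_pair"),
               "even-length")
})

test_that("connectome export writes weighted directed graphs without zero edges", {
  tm <- transition_matrix(reference_dlob_string_1())
  jpath <- withr::local_tempfile(fileext = ".json")
  export_connectome(tm, jpath, "json")
  cx <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(sort(unlist(cx$nodes)), sort(c("FL", "FR", "OL", "OR",
                                              "PL", "PR", "TL", "TR")))
  expect_equal(sum(cx$edges$weight), 41)
  expect_true(all(cx$edges$weight > 0))
  expect_equal(nrow(cx$edges), sum(tm > 0))

  dpath <- withr::local_tempfile(fileext = ".dot")
  export_connectome(tm, dpath, "dot")
  expect_true(file.size(dpath) > 0)
  gpath <- withr::local_tempfile(fileext = ".graphml")
  export_connectome(tm, gpath, "graphml")
  g <- igraph::read_graph(gpath, format = "graphml")
  expect_equal(igraph::ecount(g), sum(tm > 0))
  expect_equal(sum(igraph::E(g)$weight), 41)
})

test_that("dlob_report bundles string, histogram, entropy and transitions", {
  m <- default_montage()
  rep <- dlob_report(c(2, 30, 93), m, source_kind = "min_distance")
  expect_length(rep$string, 6L)
  expect_equal(sum(rep$histogram), 6L)
  expect_equal(rep$entropy, shannon_entropy(rep$string))
  expect_equal(sum(rep$transitions), 5L)
})
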