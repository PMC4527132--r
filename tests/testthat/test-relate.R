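test_that("children assign to the maximal-overlap parent with documented ties", {
  parents <- matrix(0L, 12, 12)
  parents[1:6, 1:12] <- 1L
  parents[7:12, 1:12] <- 2L
  children <- matrix(0L, 12, 12)
  children[2:4, 2:4] <- 1L          # wholly inside parent 1
  children[5:8, 2:4] <- 2L          # 6 px in parent 1, 6 px in parent 2: tie
  children[4:8, 8:10] <- 3L         # 9 px in parent 1... rows 4:6 =9, 7:8=6
  rel <- relate_objects(parents, children)
  expect_equal(rel$children$parent_label, c(1L, 1L, 1L))
  expect_equal(rel$children$overlap_px[1], 9L)      # full child area
  expect_equal(rel$children$overlap_px[2], 6L)      # tie -> smaller label
  expect_equal(rel$children$overlap_px[3], 9L)
  expect_equal(rel$parents$child_count, c(3L, 0L))
})

test_that("hand-constructed 12x12 overlap counts match an exhaustive oracle", {
  set.seed(61)
  parents <- matrix(sample(0:2, 144, replace = TRUE, prob = c(.3, .35, .35)),
                    12, 12)
  children <- matrix(sample(0:3, 144, replace = TRUE), 12, 12)
  rel <- relate_objects(parents, children)
  for (ch in 1:3) {
    ov <- vapply(1:2, function(p) sum(children == ch & parents == p), 0L)
    if (all(ov == 0L)) {
      expect_equal(rel$children$parent_label[ch], 0L)
    } else {
      best <- which(ov == max(ov))[1L]  # smallest label among ties
      expect_equal(rel$children$parent_label[ch], best)
      expect_equal(rel$children$overlap_px[ch], max(ov))
    }
  }
})

test_that("a child on pure background stays unassigned and is conserved", {
  parents <- matrix(0L, 8, 8); parents[1:3, 1:3] <- 1L
  children <- matrix(0L, 8, 8); children[6:7, 6:7] <- 1L
  rel <- relate_objects(parents, children)
  expect_equal(rel$children$parent_label, 0L)
  expect_equal(sum(rel$parents$child_count), 0L)
  # conservation: assigned + unassigned = total children
  expect_equal(sum(rel$children$parent_label > 0L) +
               sum(rel$children$parent_label == 0L), nrow(rel$children))
})

test_that("relating a label map to itself is the identity with full overlap", {
  set.seed(62)
  lm <- connected_components(matrix(as.integer(runif(225) < 0.3), 15, 15))
  rel <- relate_objects(lm, lm)
  areas <- tabulate(lm[lm > 0])
  expect_equal(rel$children$parent_label, rel$children$child_label)
  expect_equal(rel$children$overlap_px, areas)
  expect_true(all(rel$parents$child_count == 1L))
})

test_that("relate_objects rejects mismatched shapes", {
  expect_error(relate_objects(matrix(0L, 4, 4), matrix(0L, 5, 4)),
               "dimensions", class = "srseg_error_dimension")
})

test_that("histogram frequencies, mode and empty-parent handling", {
  parents <- matrix(0L, 9, 30)
  parents[, 1:10] <- 1L; parents[, 11:20] <- 2L; parents[, 21:30] <- 3L
  children <- matrix(0L, 9, 30)
  # parent1: 8 children, parent2: 8, parent3: 7 (single-pixel children)
  k <- 0L
  for (p in 1:3) for (i in seq_len(c(8, 8, 7)[p])) {
    k <- k + 1L
    children[1 + (i - 1) %% 9, (p - 1) * 10 + 1 + 2 * ((i - 1) %/% 9)] <- k
  }
  rel <- relate_objects(parents, children)
  h <- children_per_parent_histogram(rel)
  expect_equal(h$child_count, c(7L, 8L))
  expect_equal(h$frequency, c(1L, 2L))
  expect_equal(histogram_mode(h), 8L)
  expect_equal(sum(h$frequency), nrow(rel$parents))
  # empty parents contribute a 0 bin when included
  children2 <- children; children2[children2 > 0L & parents == 3L] <- 0L
  rel2 <- relate_objects(parents, children2)
  h_inc <- children_per_parent_histogram(rel2, include_empty_parents = TRUE)
  h_exc <- children_per_parent_histogram(rel2, include_empty_parents = FALSE)
  expect_true(0L %in% h_inc$child_count)
  expect_false(0L %in% h_exc$child_count)
})

test_that("histogram mode is invariant under parent label permutation", {
  set.seed(63)
  parents <- connected_components(matrix(as.integer(runif(400) < 0.25), 20, 20))
  children <- connected_components(matrix(as.integer(runif(400) < 0.4), 20, 20))
  h1 <- children_per_parent_histogram(relate_objects(parents, children))
  perm <- sample(max(parents))
  permuted <- parents
  permuted[parents > 0L] <- perm[parents[parents > 0L]]
  h2 <- children_per_parent_histogram(relate_objects(permuted, children))
  expect_equal(histogram_mode(h1), histogram_mode(h2))
  expect_equal(h1$frequency, h2$frequency)
})

test_that("mean children per parent averages over all parents", {
  parents <- matrix(0L, 4, 8); parents[, 1:4] <- 1L; parents[, 5:8] <- 2L
  children <- matrix(0L, 4, 8); children[1, 1] <- 1L; children[2, 2] <- 2L
  rel <- relate_objects(parents, children)
  expect_equal(mean_children_per_parent(rel), 1.0)  # counts {2, 0}
  expect_equal(mean_children_per_parent(rel),
               sum(rel$parents$child_count) / nrow(rel$parents))
  empty <- relate_objects(matrix(0L, 3, 3), matrix(0L, 3, 3))
  expect_error(mean_children_per_parent(empty), "no parents",
               class = "srseg_error_degenerate")
})
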