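proto2 <- function() {
  signature_set(matrix(c(1, 2, 3, 4, 4, 3, 2, 1), 4, 2,
                       dimnames = list(letters[1:4], c("P1", "P2"))))
}

test_that("prototypes average signatures per class", {
  sig <- signature_set(matrix(c(1, 2, 3, 1, 2, 3, 9, 8, 7), 3, 3,
                              dimnames = list(letters[1:3], c("a1", "a2", "b"))),
                       class_labels = c("A", "A", "B"))
  pro <- make_prototypes(sig)
  expect_equal(colnames(pro$matrix), c("A", "B"))
  expect_equal(unname(pro$matrix[, "A"]), c(1, 2, 3))
  expect_equal(unname(pro$matrix[, "B"]), c(9, 8, 7))
  # hand average of three distinct signatures in one class
  sig3 <- signature_set(matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3, 3,
                               dimnames = list(letters[1:3], c("x", "y", "z"))),
                        class_labels = rep("C", 3))
  expect_equal(unname(make_prototypes(sig3)$matrix[, 1]), rep(1 / 3, 3))
  # no classes -> identity
  expect_identical(make_prototypes(proto2())$matrix, proto2()$matrix)
})

test_that("classification assigns by max correlation with floor and background rules", {
  vals <- array(0, c(3, 1, 4))
  vals[1, 1, ] <- c(1, 2, 3, 4) * 2 + 1  # positive affine image of P1 -> r = 1
  vals[2, 1, ] <- -c(1, 2, 3, 4)         # anti-correlated with P1
  fld <- make_field(vals, genes = letters[1:4], normalized = TRUE)
  ct <- classify_pixels(fld, proto2(), min_corr = 0.6)
  expect_equal(ct$labels$labels[1, 1], 1L)
  expect_equal(ct$max_corr[1, 1], 1)
  expect_equal(ct$labels$labels[2, 1], 2L)  # anti-P1 is exactly P2 here
  expect_equal(ct$labels$labels[3, 1], -1L) # background stays unclassified

  single <- signature_set(proto2()$matrix[, 1, drop = FALSE])
  ct1 <- classify_pixels(fld, single, min_corr = 0.6)
  expect_equal(ct1$labels$labels[2, 1], -1L)  # max r = -1 < floor
})

test_that("classification matches the brute-force per-pixel argmax", {
  set.seed(50)
  for (i in 1:5) {
    fld <- make_field(array(rnorm(12 * 10 * 5), c(12, 10, 5)),
                      normalized = TRUE)
    P <- signature_set(matrix(rnorm(20), 5, 4,
                              dimnames = list(fld$genes, paste0("P", 1:4))))
    ct <- classify_pixels(fld, P, min_corr = 0.3)
    expect_identical(ct$labels$labels, bf_classify(fld, P, 0.3))
  }
  fld3 <- make_field(array(rnorm(6 * 5 * 3 * 4), c(6, 5, 3, 4)),
                     normalized = TRUE)
  P3 <- signature_set(matrix(rnorm(12), 4, 3,
                             dimnames = list(fld3$genes, paste0("P", 1:3))))
  expect_identical(classify_pixels(fld3, P3, 0.2)$labels$labels,
                   bf_classify(fld3, P3, 0.2))
})

test_that("classification is invariant to positive affine pixel transforms", {
  set.seed(51)
  vals <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  fld <- make_field(vals, normalized = TRUE)
  P <- signature_set(matrix(rnorm(15), 5, 3,
                            dimnames = list(fld$genes, paste0("P", 1:3))))
  ct0 <- classify_pixels(fld, P, 0.3)
  a <- matrix(runif(64, 0.5, 3), 8, 8)
  b <- matrix(rnorm(64), 8, 8)
  vals2 <- vals * array(a, c(8, 8, 5)) + array(b, c(8, 8, 5))
  ct1 <- classify_pixels(make_field(vals2, normalized = TRUE), P, 0.3)
  expect_identical(ct0$labels$labels, ct1$labels$labels)
})

test_that("argmax ties break towards the lowest prototype index", {
  vals <- array(c(1, 2, 3, 4), c(1, 1, 4))
  fld <- make_field(vals, genes = letters[1:4], normalized = TRUE)
  dup <- signature_set(matrix(c(1, 2, 3, 4, 1, 2, 3, 4), 4, 2,
                              dimnames = list(letters[1:4], c("first", "second"))))
  ct <- classify_pixels(fld, dup, 0.5)
  expect_equal(ct$labels$labels[1, 1], 1L)
})

test_that("raising the floor only grows the unclassified set", {
  set.seed(52)
  fld <- make_field(array(rnorm(10 * 10 * 5), c(10, 10, 5)),
                    normalized = TRUE)
  P <- signature_set(matrix(rnorm(15), 5, 3,
                            dimnames = list(fld$genes, paste0("P", 1:3))))
  lo <- classify_pixels(fld, P, 0.2)$labels$labels
  hi <- classify_pixels(fld, P, 0.6)$labels$labels
  expect_true(all(hi[hi != -1L] == lo[hi != -1L]))
  expect_true(all(lo[hi == -1L & lo != -1L] > 0))
  expect_gte(sum(hi == -1L), sum(lo == -1L))
})

test_that("gene vocabularies align by name with a warning on partial overlap", {
  fld <- make_field(array(rnorm(4 * 4 * 4), c(4, 4, 4)),
                    genes = c("a", "b", "c", "d"), normalized = TRUE)
  P_extra <- signature_set(matrix(rnorm(10), 5, 2,
                                  dimnames = list(c("a", "b", "c", "d", "e"),
                                                  c("P1", "P2"))))
  expect_warning(classify_pixels(fld, P_extra, 0.3), "shared genes")
  P_tiny <- signature_set(matrix(rnorm(2), 1, 2,
                                 dimnames = list("a", c("P1", "P2"))))
  expect_error(classify_pixels(fld, P_tiny, 0.3), "fewer than 2")
  raw <- make_field(array(runif(4 * 4 * 4), c(4, 4, 4)))
  expect_error(classify_pixels(raw, P_extra, 0.3), "normalized")
})

test_that("guided and de novo maps agree when centroids equal the reference", {
  set.seed(53)
  fld <- make_field(array(rnorm(6 * 6 * 5), c(6, 6, 5)), normalized = TRUE)
  cen <- signature_set(matrix(rnorm(15), 5, 3,
                              dimnames = list(fld$genes, c("C1", "C2", "C3"))),
                       provenance = "de novo")
  fake_result <- list(centroids = cen)
  g <- guided_map(fld, cen, min_corr = 0.3)
  d <- de_novo_map(fld, fake_result, min_corr = 0.3)
  expect_identical(g$labels$labels, d$labels$labels)
})
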