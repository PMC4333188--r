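test_that("likelihood ratio handles proportional, zero, and degenerate counts", {
  expect_identical(likelihood_ratio(8250, 2705844), 1)
  expect_identical(likelihood_ratio(0, 1234), 0)
  expect_warning(L <- likelihood_ratio(10, 0), "infinite")
  expect_identical(L, Inf)
  expect_warning(L0 <- likelihood_ratio(0, 0), "undefined")
  expect_true(is.nan(L0))
  expect_error(likelihood_ratio(-1, 5), "non-negative")
  expect_error(likelihood_ratio(1, 1, g_plus = 0), "positive")
})

test_that("likelihood ratio is homogeneous in the prediction counts", {
  withr::local_seed(13)
  for (rep in 1:20) {
    p <- sample(1:500, 1); m <- sample(1:500, 1); s <- sample(2:9, 1)
    expect_equal(likelihood_ratio(s * p, s * m), likelihood_ratio(p, m))
  }
})

test_that("gold-standard hit counting matches a per-pair membership scan", {
  pos <- pair_keys(sprintf("g%03d", 1:40), sprintf("h%03d", 1:40))
  neg <- pair_keys(sprintf("g%03d", 1:60), sprintf("n%03d", 1:60))

  disjoint <- pair_keys("x1", "x2")
  hd <- count_gs_hits(disjoint, pos, neg)
  expect_equal(c(hd$p_plus, hd$p_minus), c(0L, 0L))

  hs <- count_gs_hits(pos[1:7], pos, neg)  # pred subset of the positives
  expect_equal(c(hs$p_plus, hs$p_minus), c(7L, 0L))
  expect_equal(c(hs$g_plus, hs$g_minus), c(40L, 60L))  # defaults: set sizes
  hc <- count_gs_hits(pos[1:7], pos, neg, g_plus = 8250, g_minus = 2705844)
  expect_equal(c(hc$g_plus, hc$g_minus), c(8250L, 2705844L))

  withr::local_seed(17)
  for (rep in 1:10) {
    pred <- sample(c(pos, neg, disjoint), 30)
    h <- count_gs_hits(pred, pos, neg)
    expect_equal(h$p_plus, sum(vapply(unique(pred), `%in%`, logical(1), pos)))
    expect_equal(h$p_minus, sum(vapply(unique(pred), `%in%`, logical(1), neg)))
  }
  expect_error(count_gs_hits(disjoint, pos, pos), "disjoint")
})

test_that("reference hit ratio is the percentage of confirmed predictions", {
  ref <- pair_keys(sprintf("r%03d", 1:50), sprintf("s%03d", 1:50))
  expect_equal(reference_hit_ratio(ref[1:10], ref), 100)
  expect_equal(reference_hit_ratio(pair_keys("z1", "z2"), ref), 0)
  withr::local_seed(23)
  pred <- c(sample(ref, 12), pair_keys(sprintf("u%d", 1:6), sprintf("w%d", 1:6)))
  expect_equal(reference_hit_ratio(pred, ref), 100 * 12 / 18)
  expect_error(reference_hit_ratio(character(0), ref), "empty")
})

test_that("overlap statistics are symmetric and consistent with set algebra", {
  a <- pair_keys(sprintf("a%03d", 1:30), sprintf("b%03d", 1:30))
  b <- c(a[1:12], pair_keys(sprintf("c%03d", 1:8), sprintf("d%03d", 1:8)))

  st <- overlap_stats(a, b)
  expect_equal(st$intersection, 12L)
  expect_equal(st$union, length(union(a, b)))
  expect_equal(st$union, st$size_a + st$size_b - st$intersection)
  expect_equal(st$ratio_percent, 100 * 12 / st$union)

  st_rev <- overlap_stats(b, a)
  expect_equal(st_rev[c("intersection", "union", "ratio_percent")],
               st[c("intersection", "union", "ratio_percent")])

  expect_equal(overlap_stats(a, a)$ratio_percent, 100)
  expect_equal(overlap_stats(a[1:5], a[6:10])$ratio_percent, 0)
  empty <- overlap_stats(character(0), character(0))
  expect_equal(c(empty$union, empty$ratio_percent), c(0, 0))
})

test_that("annotation screening requires a shared keyword-matching term", {
  ann <- data.frame(
    protein = c("A", "B", "A", "B", "C", "D", "C", "E", "F"),
    term_id = c("T1", "T1", "T9", "T9", "T2", "T2", "T9", "T3", "T3"),
    term_name = c("proteasome complex", "proteasome complex",
                  "cytoplasm", "cytoplasm",
                  "spliceosomal COMPLEX", "spliceosomal COMPLEX",
                  "cytoplasm", "nucleus", "nucleus"),
    stringsAsFactors = FALSE)

  hit <- annotation_hit_ratio(pair_keys("A", "B"), ann)
  expect_equal(hit$hits, 1L)
  expect_equal(hit$ratio_percent, 100)
  # shared cytoplasm only: no hit; keyword match is case-insensitive
  res <- annotation_hit_ratio(pair_keys(c("B", "C", "E"), c("C", "D", "F")), ann)
  expect_equal(res$hits, 1L)   # only (C,D) share a "complex" term
  expect_equal(res$ratio_percent, 100 / 3)
  expect_error(annotation_hit_ratio(character(0), ann), "empty")
})

test_that("annotation hits match a brute-force shared-term double loop", {
  withr::local_seed(29)
  prots <- sprintf("p%02d", 1:15)
  ann <- data.frame(
    protein = sample(prots, 60, replace = TRUE),
    term_id = sprintf("T%d", sample(1:8, 60, replace = TRUE)),
    stringsAsFactors = FALSE)
  ann$term_name <- ifelse(as.integer(sub("T", "", ann$term_id)) <= 4,
                          paste(ann$term_id, "protein complex"),
                          paste(ann$term_id, "membrane"))
  cmb <- utils::combn(prots, 2)
  pred <- paste(cmb[1, ], cmb[2, ], sep = "\t")

  res <- annotation_hit_ratio(pred, ann)
  kw <- ann[grepl("complex", ann$term_name), ]
  brute <- 0L
  for (i in seq_along(pred)) {
    ta <- kw$term_id[kw$protein == cmb[1, i]]
    tb <- kw$term_id[kw$protein == cmb[2, i]]
    if (length(intersect(ta, tb))) brute <- brute + 1L
  }
  expect_equal(res$hits, brute)
  expect_equal(res$ratio_percent, 100 * brute / length(pred))
})
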