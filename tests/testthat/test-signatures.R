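make_stats <- function(med, class = "X") {
  tibble::tibble(class = class, feature = sbs96_contexts(),
                 n = 2L, median = med, mean = med, sd = 0,
                 min = med, max = med)
}

test_that("informative signatures average frequencies and clip relevance", {
  ctx <- sbs96_contexts()
  # two samples: one-hot counts on contexts 1 and 2
  counts <- matrix(0L, 2, 96, dimnames = list(NULL, ctx))
  counts[1, 1] <- 10L; counts[2, 2] <- 30L
  fx <- dplyr::bind_cols(tibble::tibble(sample_id = c("a", "b")),
                         tibble::as_tibble(counts))
  med <- rep(-0.01, 96); med[1] <- 0.2
  sig <- informative_signature(fx, make_stats(med), cancer_type = "X")
  expect_equal(sig$frequency[1:3], c(0.5, 0.5, 0))
  expect_equal(sum(sig$frequency), 1, tolerance = 1e-9)
  expect_equal(sig$relevance[1], 0.2)
  expect_true(all(sig$relevance[-1] == 0))  # negative medians clipped
  expect_equal(attr(sig, "cancer_type"), "X")
  # identical samples reproduce their common frequency vector
  sig2 <- informative_signature(fx[c(1, 1), ], make_stats(med), "X")
  expect_equal(sig2$frequency, as.numeric(counts[1, ] / 10))
  # zero-mutation samples are excluded with a warning
  fx0 <- fx; fx0[2, -1] <- 0L
  expect_warning(informative_signature(fx0, make_stats(med), "X"),
                 "zero mutations")
})

test_that("feature-focused distance is the halved L1 on unit-sum vectors", {
  a <- c(0.5, 0.5, 0, 0); b <- c(0, 0, 1, 0)
  expect_equal(feature_focused_distance(a, a), 0)
  expect_equal(feature_focused_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(feature_focused_distance(a, b), 1)
  expect_equal(featurewise_abs_similarity(a, b), 0)
  expect_equal(featurewise_abs_similarity(a, a), 1)
  expect_error(feature_focused_distance(a, b[1:3]), "length")
})

test_that("feature-focused distance is a metric on random unit-sum triples", {
  withr::local_seed(77)
  for (r in 1:50) {
    x <- stats::runif(16); x <- x / sum(x)
    y <- stats::runif(16); y <- y / sum(y)
    z <- stats::runif(16); z <- z / sum(z)
    dxy <- feature_focused_distance(x, y)
    dyz <- feature_focused_distance(y, z)
    dxz <- feature_focused_distance(x, z)
    expect_gte(dxy, 0); expect_lte(dxy, 1)
    expect_equal(dxy, feature_focused_distance(y, x))
    expect_lte(dxz, dxy + dyz + 1e-12)
  }
  expect_equal(feature_focused_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
})

test_that("pearson correlation matches a textbook two-pass computation", {
  two_pass <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  withr::local_seed(5)
  for (r in 1:20) {
    x <- stats::rnorm(30); y <- stats::rnorm(30)
    expect_equal(pearson_correlation(x, y), two_pass(x, y),
                 tolerance = 1e-12)
  }
  x <- c(1, 2, 3)
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  expect_equal(pearson_correlation(x, c(2, 4, 6)), 1)
  expect_warning(p <- pearson_correlation(x, c(1, 1, 1)), "zero-variance")
  expect_true(is.na(p))
})

toy_sig <- function(freq, rel, type = "T") {
  out <- tibble::tibble(context = paste0("k", seq_along(freq)),
                        frequency = freq, relevance = rel)
  structure(out, class = c("informative_signature", class(out)),
            cancer_type = type)
}

test_that("relevance-weighted distance is symmetric with a one-hot worst case", {
  A <- toy_sig(c(1, 0, 0), c(1, 0, 0))
  B <- toy_sig(c(0, 1, 0), c(0, 1, 0))
  expect_equal(relevance_weighted_distance(A, A), 0)
  expect_equal(relevance_weighted_distance(A, B), 1)
  C <- toy_sig(c(0.2, 0.3, 0.5), c(0.5, 0.2, 0.1))
  D <- toy_sig(c(0.6, 0.1, 0.3), c(0.1, 0.1, 0.4))
  expect_equal(relevance_weighted_distance(C, D),
               relevance_weighted_distance(D, C))
  Z <- toy_sig(c(1, 0, 0), c(0, 0, 0))
  expect_error(relevance_weighted_distance(A, Z), "all-zero")
})

test_that("relevance-weighted distance stays within [0, 1] on random draws", {
  withr::local_seed(123)
  n <- 10000
  worst <- 0
  for (r in seq_len(n)) {
    fA <- stats::runif(96); fA <- fA / sum(fA)
    fB <- stats::runif(96); fB <- fB / sum(fB)
    rA <- stats::runif(96); rB <- stats::runif(96)
    A <- toy_sig(fA, rA); B <- toy_sig(fB, rB)
    d <- relevance_weighted_distance(A, B)
    worst <- max(worst, d)
  }
  expect_lte(worst, 1)
  expect_gt(worst, 0)
})

test_that("combination fitting recovers members and mixtures of the catalog", {
  ctx <- sbs96_contexts()
  catalog <- make_signature_set(4, seed = 9)
  target <- toy_sig(catalog$sig02, rep(1 / 96, 96), "self")
  target$context <- ctx
  fit <- fit_signature_combination(target, catalog)
  expect_equal(fit$distance, 0, tolerance = 1e-12)
  expect_true(fit$fits)
  expect_equal(fit$signatures[1], "sig02")

  mix <- 0.5 * catalog$sig01 + 0.5 * catalog$sig03
  t2 <- toy_sig(mix, rep(1 / 96, 96), "mix")
  t2$context <- ctx
  fit2 <- fit_signature_combination(t2, catalog, weight_step = 0.05)
  expect_equal(fit2$distance, 0, tolerance = 1e-12)
  expect_setequal(fit2$signatures, c("sig01", "sig03"))
  expect_equal(sort(fit2$weights), c(0.5, 0.5))
  expect_true(fit2$fits)
  expect_equal(nrow(tidy(fit2)), 2L)
})

test_that("disjoint one-hot catalogs cannot fit a one-hot target", {
  catalog <- tibble::tibble(context = paste0("k", 1:6),
                            s1 = c(0, 1, 0, 0, 0, 0),
                            s2 = c(0, 0, 1, 0, 0, 0))
  target <- toy_sig(c(1, 0, 0, 0, 0, 0), c(1, 0, 0, 0, 0, 0))
  fit <- fit_signature_combination(target, catalog)
  expect_equal(fit$distance, 1)  # best equals the maximal distance
  expect_false(fit$fits)
})

test_that("grid fitting matches exhaustive enumeration on toy catalogs", {
  # Independent oracle: plain loops over singles and pairs on the grid.
  oracle_best <- function(f, r, S, step) {
    r <- pmax(r, 0); r <- r / sum(r)
    score <- function(cand) sum(2 * r * abs(f - cand)) / (2 * max(r))
    best <- Inf
    for (i in seq_len(ncol(S))) best <- min(best, score(S[, i]))
    ws <- seq(step, 1 - step, by = step)
    if (ncol(S) >= 2) {
      for (i in 1:(ncol(S) - 1)) for (j in (i + 1):ncol(S)) {
        for (w in ws) best <- min(best, score(w * S[, i] + (1 - w) * S[, j]))
      }
    }
    best
  }
  withr::local_seed(31)
  for (r in 1:5) {
    S <- matrix(stats::runif(6 * 4), 6, 4)
    S <- sweep(S, 2, colSums(S), "/")
    catalog <- dplyr::bind_cols(tibble::tibble(context = paste0("k", 1:6)),
                                tibble::as_tibble(S, .name_repair = ~
                                                    paste0("s", 1:4)))
    f <- stats::runif(6); f <- f / sum(f)
    rel <- stats::runif(6)
    target <- toy_sig(f, rel)
    fit <- fit_signature_combination(target, catalog, weight_step = 0.1)
    expect_equal(fit$distance,
                 oracle_best(f, rel, S, 0.1), tolerance = 1e-12)
  }
})
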