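test_that("VAF closed forms", {
  A <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]]
  W <- diag(2); H <- A
  expect_equal(vaf(A, W, H), 100)
  expect_equal(vaf(A, W, matrix(0, 2, 2)), 0)
  WH <- matrix(c(1, 3, 2, 0), 2, 2)  # [[1,2],[3,0]]
  expect_equal(vaf(A, diag(2), WH), 100 * (1 - 16 / 30))
  expect_error(vaf(matrix(0, 2, 2), W, H), "undefined")
})

test_that("MSE closed forms", {
  A <- matrix(1, 3, 4)
  expect_equal(recon_mse(A, matrix(1, 3, 1), matrix(1, 1, 4)), 0)
  expect_equal(recon_mse(A, matrix(1, 3, 1), matrix(1 - 0.2, 1, 4)), 0.04)
  A2 <- matrix(c(1, 1, 1, 1), 2, 2)
  WH <- matrix(c(1, 1, 0.9, 0.7), 2, 2)  # residuals 0,0,0.1,0.3
  expect_equal(recon_mse(A2, diag(2), WH), 0.025)
})

test_that("cosine similarity basics", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0, 1), c(1, 1, 0)), 0.5)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("NMF represents a rank-1 outer product exactly", {
  w <- c(0.2, 1, 0.5, 0)
  h <- seq(0.1, 2, length.out = 50)
  A <- outer(w, h)
  fit <- fit_nmf(A, 1, restarts = 3, seed = 1)
  expect_gte(fit$vaf_percent, 99.9)
  expect_lte(fit$mse, 1e-8)
  sel <- select_order(A, restarts = 2, seed = 1)
  expect_equal(sel$n, 1L)
  expect_true(sel$satisfied)
})

test_that("NMF is deterministic given a seed and validates inputs", {
  set.seed(3)
  A <- matrix(runif(8 * 60), 8, 60)
  f1 <- fit_nmf(A, 3, restarts = 4, seed = 9)
  f2 <- fit_nmf(A, 3, restarts = 4, seed = 9)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
  expect_true(all(f1$W >= 0) && all(f1$H >= 0))
  expect_equal(unname(apply(f1$W, 2, max)), rep(1, 3))
  expect_error(fit_nmf(A, 0), "must lie")
  expect_error(fit_nmf(A, 9), "must lie")
  expect_error(fit_nmf(-A, 2), "non-negative")
})

test_that("trial concatenation records boundaries and inverts exactly", {
  t1 <- tibble::tibble(time_s = (0:99) / 100, m1 = runif(100), m2 = runif(100))
  t2 <- tibble::tibble(time_s = (0:49) / 100, m1 = runif(50), m2 = runif(50))
  cc <- concat_trials(list(t1, t2))
  expect_equal(nrow(cc), 150)
  expect_equal(attr(cc, "boundaries"), c(100, 150))
  back <- split_trials(cc)
  expect_equal(back[[1]], t1, ignore_attr = TRUE)
  expect_equal(back[[2]], t2, ignore_attr = TRUE)
  expect_equal(concat_trials(list(t1))[c("m1", "m2")], t1[c("m1", "m2")],
               ignore_attr = TRUE)
  t3 <- tibble::tibble(time_s = (0:49) / 100, other = runif(50))
  expect_error(concat_trials(list(t1, t3)), "same muscle channels")
})

test_that("temporal estimation under fixed W recovers consistent systems", {
  set.seed(4)
  W <- matrix(runif(8 * 3), 8, 3)
  H <- matrix(runif(3 * 40), 3, 40)
  A <- W %*% H
  Hhat <- estimate_temporal(A, W)
  expect_equal(Hhat, H, tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(estimate_temporal(matrix(0, 8, 5), W) == 0))
  # overdetermined consistent single frame: ls solution is exact
  W2 <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2)
  a <- matrix(c(1, 2, 3), 3, 1)
  expect_equal(as.numeric(estimate_temporal(a, W2)), c(1, 2), tolerance = 1e-10)
  # brute-force grid oracle around the solution confirms optimality
  grid <- expand.grid(h1 = seq(0, 2, 0.05), h2 = seq(1, 3, 0.05))
  sse <- apply(grid, 1, function(g) sum((a - W2 %*% g)^2))
  expect_equal(unname(unlist(grid[which.min(sse), ])), c(1, 2),
               tolerance = 1e-8)
  expect_error(estimate_temporal(a, cbind(W2[, 1], W2[, 1])),
               "rank-deficient")
})

test_that("temporal estimates are non-negative even when ls would not be", {
  W <- cbind(c(1, 1, 0), c(1, 0, 1))
  a <- c(0, 1, -0.0)  # unconstrained ls gives a negative coefficient
  a <- matrix(c(0.2, 1, 0), 3, 1)
  h <- estimate_temporal(a, W)
  expect_true(all(h >= 0))
})

test_that("synergy matching recovers permutations and beats greedy", {
  set.seed(6)
  W <- matrix(runif(8 * 4), 8, 4)
  colnames(W) <- paste0("w", 1:4)
  perm <- c(3, 1, 4, 2)
  Wb <- W[, perm]
  colnames(Wb) <- paste0("v", 1:4)
  m <- match_synergies(W, Wb)
  expect_equal(m$assignment$similarity, rep(1, 4), tolerance = 1e-12)
  # Wb column j is Wa column perm[j], so Wa column i pairs with v_{perm^-1(i)}
  expect_equal(m$assignment$b, paste0("v", match(1:4, perm)))

  # brute-force oracle: optimal assignment total over all permutations,
  # and a greedy best-first baseline that the optimum must dominate
  greedy_total <- function(S) {
    tot <- 0
    for (k in seq_len(nrow(S))) {
      ij <- which(S == max(S), arr.ind = TRUE)[1, ]
      tot <- tot + S[ij[1], ij[2]]
      S[ij[1], ] <- -Inf
      S[, ij[2]] <- -Inf
    }
    tot
  }
  brute_total <- function(S) {
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
    max(vapply(perms, function(p) sum(S[cbind(1:3, p)]), numeric(1)))
  }
  strict_case <- FALSE
  for (s in 1:40) {
    set.seed(s)
    Wa <- matrix(runif(5 * 3), 5, 3)
    Wb <- matrix(runif(5 * 3), 5, 3)
    mm <- match_synergies(Wa, Wb)
    expect_equal(mm$total, brute_total(mm$similarity), tolerance = 1e-12)
    if (mm$total > greedy_total(mm$similarity) + 1e-9) strict_case <- TRUE
  }
  expect_true(strict_case)
  expect_error(match_synergies(matrix(1, 4, 2), matrix(1, 5, 2)),
               "same muscle rows")
})

test_that("best-match report mirrors the per-column maxima", {
  Wa <- cbind(a1 = c(1, 0, 0), a2 = c(0, 1, 0))
  Wb <- cbind(b1 = c(1, 1, 0), b2 = c(0, 0, 1))
  m <- match_synergies(Wa, Wb)
  expect_equal(m$best$b, c("b1", "b1"))
})

test_that("NMF recovers the generator's spatial patterns from noiseless envelopes", {
  cfg <- synth_config(cycles_per_strategy = 2, envelope_noise_sd = 0,
                      baseline_envelope = 0, carrier_baseline_sd = 0)
  trials <- simulate_corpus(cfg)
  env <- concat_trials(lapply(trials, function(tr) {
    downsample_pool(tr$envelopes, tr$fs, 100)
  }))
  fit <- fit_nmf(env, 4, restarts = 10, seed = 2)
  m <- match_synergies(cfg$true_spatial, fit$W)
  expect_true(all(m$assignment$similarity >= 0.95))
})

test_that("higher model order does not lose explained variance", {
  A <- small_activation("momentum")
  v_prev <- -Inf
  for (n in c(2, 3, 4)) {
    f <- fit_nmf(A, n, restarts = 3, seed = 5, max_iter = 800)
    expect_gte(f$vaf_percent, v_prev - 0.5)
    v_prev <- f$vaf_percent
  }
})

test_that("added envelope noise never lowers the selected synergy count", {
  # the order criterion is monotone in noise on a fixed latent structure
  for (s in 1:5) {
    clean <- synth_config(cycles_per_strategy = 1, rng_seed = 100 + s)
    noisy <- synth_config(cycles_per_strategy = 1, rng_seed = 100 + s,
                          envelope_noise_sd = 0.05)
    n_of <- function(cfg) {
      tr <- generate_trial(cfg, "momentum")
      env <- downsample_pool(tr$envelopes, tr$fs, 100)
      chans <- setdiff(names(env), "time_s")
      env[chans] <- sweep(as.matrix(env[chans]), 2,
                          apply(as.matrix(env[chans]), 2, max), "/")
      select_order(env, restarts = 2, seed = 5, max_iter = 600)$n
    }
    expect_gte(n_of(noisy), n_of(clean))
  }
})
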