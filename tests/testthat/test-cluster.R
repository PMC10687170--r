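# Hierarchical cluster-permutation statistics.

test_that("channel t-maps implement the Spearman t transform", {
  # t = rho * sqrt((n - 2) / (1 - rho^2)); rho = 0.5, n = 102 -> 5.7735
  expect_equal(statereach:::rho_to_t(0.5, 102),
               0.5 * sqrt(100 / 0.75), tolerance = 1e-10)
  expect_equal(statereach:::rho_to_t(0.5, 102), 5.7735, tolerance = 1e-4)
  # |rho| = 1 capped at the sentinel, not infinite
  expect_true(is.finite(statereach:::rho_to_t(1, 50)))
  expect_equal(statereach:::rho_to_t(-1, 50), -statereach:::T_CAP)

  set.seed(9)
  n <- 40
  arr <- array(rnorm(n * 3 * 4), dim = c(n, 3, 4))
  state <- rnorm(n)
  tm <- channel_t_map(arr, state)
  expect_equal(dim(tm), c(3, 4))
  # oracle: per pixel via stats::cor
  rho_o <- cor(state, arr[, 2, 3], method = "spearman")
  expect_equal(tm[2, 3], rho_o * sqrt((n - 2) / (1 - rho_o^2)),
               tolerance = 1e-10)

  # a pixel that is a monotone function of the state hits the cap
  arr[, 1, 1] <- exp(state)
  expect_equal(channel_t_map(arr, state)[1, 1], statereach:::T_CAP)

  expect_error(channel_t_map(arr, rep(1, n)), "constant")
  expect_error(channel_t_map(arr[1:5, , ], state[1:5]), ">= 10")
})

test_that("hierarchical averaging weighs subjects, not channels", {
  d <- c(2, 2)
  m1 <- matrix(1, 2, 2); m2 <- matrix(3, 2, 2); m3 <- matrix(5, 2, 2)
  # subject A: ten identical channels of 1s; subject B: one channel of 3s
  pop <- aggregate_hierarchical(list(rep(list(m1), 10), list(m2)))
  expect_equal(pop$t_map, matrix(2, 2, 2))   # (1 + 3) / 2, not pooled
  # one channel per subject reduces to the plain mean over subjects
  pop2 <- aggregate_hierarchical(list(list(m1), list(m2), list(m3)))
  expect_equal(pop2$t_map, matrix(3, 2, 2))
  # naive-loop oracle on random maps
  set.seed(1)
  maps <- lapply(1:3, function(s)
    lapply(seq_len(s), function(c) matrix(rnorm(6), 2, 3)))
  pop3 <- aggregate_hierarchical(maps)
  oracle <- Reduce(`+`, lapply(maps, function(chs)
    Reduce(`+`, chs) / length(chs))) / 3
  expect_equal(pop3$t_map, oracle, tolerance = 1e-12)
  expect_error(aggregate_hierarchical(maps[1]), ">= 2")
})

test_that("cluster finding uses signed 4-connectivity", {
  z <- matrix(0, 4, 4)
  expect_length(find_clusters(z, threshold = "absolute", t_thresh = 1), 0)

  z[2, 2] <- 5
  cl <- find_clusters(z, threshold = "absolute", t_thresh = 1)
  expect_length(cl, 1)
  expect_equal(length(cl[[1]]$pixels), 1)

  # checkerboard: no two supra pixels share an edge -> all singletons
  cb <- matrix(0, 4, 4)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 3
  clc <- find_clusters(cb, threshold = "absolute", t_thresh = 1)
  expect_length(clc, sum(cb > 0))

  # opposite signs never merge even when adjacent
  z2 <- matrix(0, 3, 3)
  z2[1, 1] <- 4; z2[1, 2] <- -4
  cl2 <- find_clusters(z2, threshold = "absolute", t_thresh = 1)
  expect_length(cl2, 2)
  expect_setequal(vapply(cl2, `[[`, numeric(1), "mass"), c(4, -4))

  # mass is the sum of t over the component
  z3 <- matrix(0, 3, 3)
  z3[1, 1:3] <- c(2, 3, 4)
  cl3 <- find_clusters(z3, threshold = "absolute", t_thresh = 1)
  expect_equal(cl3[[1]]$mass, 9)
})

test_that("the subject-level threshold forms pixels from a one-sample t", {
  # 4 subjects agreeing strongly at one pixel only
  d <- c(2, 2)
  mk <- function(v) matrix(c(v, 0, 0, 0), 2, 2)
  maps <- lapply(c(3.0, 3.2, 2.8, 3.1), function(v) list(mk(v)))
  pop <- aggregate_hierarchical(maps)
  cl <- find_clusters(pop, alpha = 0.05)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$pixels, 1)
  # with discordant subjects the pixel fails the threshold
  maps2 <- lapply(c(3, -3, 3, -3), function(v) list(mk(v)))
  expect_length(find_clusters(aggregate_hierarchical(maps2)), 0)
})

test_that("cluster size filter enforces time, octave, and area minima", {
  freqs <- cwt_freqs(4, 64, 6)   # 6 bins/octave -> 4 octaves span
  mk_cluster <- function(ti, fi, solid = TRUE) {
    m <- matrix(FALSE, 30, length(freqs))
    m[ti, fi] <- TRUE
    pix <- which(m)
    list(pixels = pix, mask = m, sign = 1, mass = length(pix),
         time_idx = range(ti), freq_idx = range(fi))
  }
  # 300 ms x 1.5 octaves solid: kept (6 bins x 10 bins at 50 ms, 6/oct)
  expect_true(filter_cluster_size(mk_cluster(1:6, 1:10), freqs))
  # 200 ms x 2 octaves: discarded on time
  expect_false(filter_cluster_size(mk_cluster(1:4, 1:13), freqs))
  # 300 ms x half octave: discarded on frequency
  expect_false(filter_cluster_size(mk_cluster(1:6, 1:4), freqs))
  # thin L-shape: big bounding box, area below the pixel minimum
  m <- matrix(FALSE, 30, length(freqs))
  m[1:10, 1] <- TRUE
  m[10, 1:13] <- TRUE
  pix <- which(m)
  lcl <- list(pixels = pix, mask = m, sign = 1, mass = 1,
              time_idx = c(1, 10), freq_idx = c(1, 13))
  expect_false(filter_cluster_size(lcl, freqs))  # 22 px < 5 * 6 = 30
})

test_that("FDR correction matches the Benjamini-Hochberg step-up oracle", {
  set.seed(11)
  p <- runif(40)^2 * sign(runif(40) - 0.5)
  keep <- fdr_correct(p, q = 0.015)
  # brute-force step-up oracle
  ap <- abs(p)
  ord <- order(ap)
  m <- length(p)
  thresh <- 0
  for (i in seq_len(m)) if (ap[ord[i]] <= 0.015 * i / m) thresh <- ap[ord[i]]
  expect_equal(keep, ap <= thresh)

  # all at the permutation floor survive
  expect_true(all(fdr_correct(rep(-1 / 1001, 12), q = 0.015)))
  # a single p = 0.02 is rejected at q = 0.015
  expect_false(fdr_correct(0.02, q = 0.015))
  expect_length(fdr_correct(numeric(0)), 0)
})

test_that("the permutation test recovers a planted effect with signed p", {
  target <- list(region = "A", epochs = "go_cue",
                 time_window = c(0.2, 0.8), freq_band = c(10, 60),
                 state = "error", gain = 1.5, base_amp = 1)
  subs <- lapply(1:3, function(s)
    synth_subject_spect(100 + s, n_trials = 30,
                        targets = list(target),
                        freqs = cwt_freqs(4, 80, 4)))
  sb <- lapply(subs, function(s) list(s$spect$c1$go_cue,
                                      s$spect$c2$go_cue))
  st <- lapply(subs, function(s) s$states$x_se_z)
  res <- permutation_test(sb, st, n_perm = 99, seed = 5)
  expect_equal(res$n_subjects, 3)
  expect_gt(length(res$clusters), 0)
  big <- res$clusters[[which.max(sapply(res$clusters,
                                        function(c) abs(c$mass)))]]
  expect_equal(big$sign, 1)                   # power rises with the state
  expect_equal(abs(big$p_signed), 1 / 100)    # beats all 99 null maxima
  expect_true(all(abs(sapply(res$clusters, `[[`, "p_signed")) >= 1 / 100))
})

test_that("cluster grouping merges overlapping bands and labels patterns", {
  freqs <- cwt_freqs(1, 200, 6)
  bin_at <- function(f) which.min(abs(freqs - f))
  df <- data.frame(region = c("A", "A", "B"),
                   epoch = c("go_cue", "movement_onset", "go_cue"),
                   mass = c(10, 8, -5),
                   p_signed = c(0.001, 0.002, -0.001),
                   stringsAsFactors = FALSE)
  df$freq_bins <- list(bin_at(4):bin_at(8),      # theta in A
                       bin_at(5):bin_at(7),      # overlapping theta in A
                       bin_at(60):bin_at(200))   # gamma span in B
  g <- group_and_label(df, freqs, all_epochs = c("go_cue",
                                                 "movement_onset"))
  expect_equal(nrow(g), 2)
  a <- g[g$region == "A", ]
  expect_equal(a$band, "theta")
  expect_equal(a$temporal_pattern, "persistent")  # spans both epochs
  expect_equal(a$direction, 1)
  b <- g[g$region == "B", ]
  expect_equal(b$temporal_pattern, "phasic")
  # 60-200 Hz with most area above 100 Hz -> hyper gamma
  expect_equal(b$band, "hyper gamma")

  # same region, disjoint bands stay separate groups
  df2 <- df[c(1, 2), ]
  df2$freq_bins <- list(bin_at(4):bin_at(8), bin_at(30):bin_at(60))
  expect_equal(nrow(group_and_label(df2, freqs)), 2)
})

test_that("canonical band mapping follows the stated boundaries", {
  expect_equal(frequency_band(c(2, 5, 10, 20, 45, 80, 150)),
               c("delta", "theta", "alpha", "beta", "low gamma",
                 "high gamma", "hyper gamma"))
})
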