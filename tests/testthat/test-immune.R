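test_that("binary field decoding hits its bounds and interior grid points", {
  expect_equal(decode_field(rep(0, 8), -3, 12), -3)
  expect_equal(decode_field(rep(1, 8), -3, 12), 12)
  expect_equal(decode_field(c(1, 0, 1), 0, 7), 5)   # LSB first: 1 + 4
  expect_error(decode_field(c(0, 1), 5, 5), "exceed")
  expect_error(decode_field(c(0, 2), 0, 1), "0/1")
})

test_that("decoding is a bijection over every 8-bit pattern", {
  seen <- numeric(256)
  for (v in 0:255) {
    bits <- as.integer(intToBits(v)[1:8])
    x <- decode_field(bits, 0, 255)
    seen[v + 1] <- x
    expect_identical(encode_field(x, 8, 0, 255), bits)
  }
  expect_equal(seen, 0:255)              # uniform grid on [0, 255]
  expect_equal(length(unique(seen)), 256)
  expect_true(all(diff(seen) > 0))       # strictly increasing
})

test_that("antibody decoding splits fields and repairs empty masks", {
  cfg <- ia_config(seed = 1)
  bits <- rep(0L, 32 * 8)
  ph <- decode_antibody(bits, cfg)
  expect_equal(ph$C, cfg$c_bounds[1])
  expect_equal(ph$r, cfg$r_bounds[1])
  expect_false(any(ph$mask))             # all fields decode to 0 < 0.5

  set.seed(9)
  repaired <- immunotexture:::.repair_antibody(bits, cfg)
  expect_true(any(decode_antibody(repaired, cfg)$mask))

  expect_error(decode_antibody(rep(0L, 10), cfg), "length")
})

test_that("population initialization is seeded and structurally valid", {
  cfg <- ia_config(n_groups = 5, bits_per_field = 8, seed = 77)
  set.seed(cfg$seed); p1 <- init_population(cfg)
  set.seed(cfg$seed); p2 <- init_population(cfg)
  expect_identical(p1, p2)
  expect_length(p1, 5)
  for (ab in p1) {
    expect_length(ab$bits, 32 * 8)
    expect_true(any(decode_antibody(ab$bits, cfg)$mask))
  }
})

test_that("cloning follows the 10x/30x protocol and mutates at 1/n per bit", {
  cfg <- ia_config(n_groups = 5, clone_general = 10, clone_best = 30,
                   seed = 3)
  set.seed(3)
  pop <- init_population(cfg)
  for (i in seq_along(pop)) pop[[i]]$affinity <- i / 10
  set.seed(11); clones <- clone_and_mutate(pop, cfg)
  expect_length(clones, 30 + 4 * 10)
  expect_equal(sum(vapply(clones, function(a) a$lineage, 0L) == 5L), 30L)
  set.seed(11); clones2 <- clone_and_mutate(pop, cfg)
  expect_identical(clones, clones2)

  # empirical flip rate over many clones approaches 1/n = 1/8
  flips <- vapply(clones, function(cl)
    sum(cl$bits != pop[[cl$lineage]]$bits), 0)
  expect_equal(mean(flips) / (32 * 8), 1 / 8, tolerance = 0.15)
  pop[[1]]$affinity <- NA_real_
  expect_error(clone_and_mutate(pop, cfg), "evaluated")
})

test_that("per-lineage selection is elitist and restores population size", {
  cfg <- ia_config(n_groups = 3, clone_general = 2, clone_best = 4, seed = 1)
  mk <- function(lineage, affinity) {
    ab <- list(bits = rep(0L, 32 * 8), lineage = lineage, affinity = affinity)
    ab
  }
  parents <- list(mk(1, 0.5), mk(2, 0.9), mk(3, 0.2))
  clones <- list(mk(1, 0.7), mk(1, 0.4), mk(2, 0.1), mk(3, 0.1))
  nxt <- select_next_generation(parents, clones, cfg)
  expect_length(nxt, 3)
  expect_equal(vapply(nxt, function(a) a$affinity, 0), c(0.7, 0.9, 0.2))
})

test_that("the optimizer is elitist, seeded and respects stop conditions", {
  cfg <- ia_config(n_groups = 5, max_generations = 40, seed = 5,
                   target_affinity = 1.0)
  res <- run_optimization(NULL, cfg, affinity_fun = surrogate_affinity)
  expect_lte(nrow(res$history), 40)
  expect_true(all(diff(res$history$best_affinity) >= 0))
  expect_equal(res$history$objective, 1 - res$history$best_affinity)

  res2 <- run_optimization(NULL, cfg, affinity_fun = surrogate_affinity)
  expect_identical(res$history, res2$history)
  expect_identical(res$best, res2$best)

  early <- run_optimization(NULL, ia_config(seed = 2, target_affinity = 0),
                            affinity_fun = surrogate_affinity)
  expect_equal(nrow(early$history), 1)
})

test_that("the optimizer converges near the surrogate optimum", {
  cfg <- ia_config(n_groups = 5, max_generations = 200, seed = 8)
  res <- run_optimization(NULL, cfg, affinity_fun = surrogate_affinity)
  ph <- res$phenotype
  # surrogate peak at log2 C = 5, log2 r = -6
  expect_equal(log2(ph$C), 5, tolerance = 0.2)
  expect_equal(log2(ph$r), -6, tolerance = 0.2)
  expect_gte(res$best$affinity, 0.99)
})

test_that("clonal selection beats equal-budget random search on the surrogate", {
  cfg <- ia_config(n_groups = 5, max_generations = 30, seed = 1)
  wins <- 0L
  for (s in 1:5) {
    cfg$seed <- s
    res <- run_optimization(NULL, cfg, affinity_fun = surrogate_sphere)
    set.seed(1000 + s)
    budget <- res$evaluations
    best_rand <- max(vapply(seq_len(budget), function(i) {
      ab <- list(bits = sample(0:1, 32 * 8, replace = TRUE))
      surrogate_sphere(ab, NULL, cfg)
    }, 0))
    if (res$best$affinity > best_rand) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("SVM affinity separates constructed data and caches determinism", {
  data <- blob_dataset(n_per_class = 15, sep = 8, seed = 2)
  cfg <- ia_config(seed = 1)
  ab <- list(bits = rep(1L, 32 * 8), lineage = 1L, affinity = NA_real_)
  a1 <- svm_affinity(ab, data, cfg)
  a2 <- svm_affinity(ab, data, cfg)
  expect_identical(a1, a2)
  # all features on, defensible parameters: blobs are separable
  ab$bits[1:16] <- c(encode_field(log2(1), 8, log2(cfg$c_bounds[1]),
                                  log2(cfg$c_bounds[2])),
                     encode_field(log2(0.03), 8, log2(cfg$r_bounds[1]),
                                  log2(cfg$r_bounds[2])))
  expect_gte(svm_affinity(ab, data, cfg), 0.95)
})

test_that("single-class data is rejected", {
  d <- blob_dataset(10, seed = 3)
  one <- d
  one$labels <- factor(rep("normal", length(d$labels)),
                       levels = levels(d$labels))
  one$labels <- droplevels(one$labels)
  expect_error(run_optimization(one, ia_config(seed = 1)), "two classes")
})
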