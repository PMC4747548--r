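test_that("GA operators behave as defined", {
  set.seed(1)
  a <- rep(c(TRUE, FALSE), 10)
  # crossover of identical parents is the parent
  expect_identical(uniform_crossover(a, a, 0.5), a)
  # zero mutation rate is the identity
  expect_identical(mutate_mask(a, 0), a)
  # all-zero mutation result gets one bit set back
  z <- rep(FALSE, 20)
  expect_equal(sum(mutate_mask(z, 0)), 1)
  # mean flips at rate 1/N match the binomial oracle within 3 s.e.
  N <- 50L
  trials <- 1e4
  set.seed(2)
  flips <- replicate(trials, {
    m <- rep(FALSE, N)
    m[1:10] <- TRUE
    sum(xor(m, mutate_mask(m, 1 / N)))
  })
  se <- sqrt(1 * (1 - 1 / N) / trials)
  expect_lt(abs(mean(flips) - 1), 3 * se + 2 / trials) # + all-zero guard slack
  # tournament returns the fittest of its k draws
  set.seed(3)
  fits <- runif(30)
  for (r in 1:50) {
    set.seed(r)
    pick <- tournament_select(fits, 3)
    set.seed(r)
    cand <- sample.int(30, 3, replace = TRUE)
    expect_equal(fits[pick], max(fits[cand]))
  }
})

test_that("fitness is deterministic, guarded, and honest about leakage", {
  tab <- tiny_table(n_kd = 15, n_fc = 15, n_compounds = 10,
                    n_informative = 2, effect_size = 3, seed = 4)
  mask <- rep(TRUE, 10)
  f1 <- ga_fitness(mask, tab, cv_folds = 5, seed = 9)
  f2 <- ga_fitness(mask, tab, cv_folds = 5, seed = 9)
  expect_identical(f1, f2)
  # empty mask is defined as fitness 0
  expect_equal(ga_fitness(rep(FALSE, 10), tab), 0)
  # a perfectly separating compound gives mean CV AUC 1
  sep <- tab
  kd <- sep$labels == 1L
  sep$values[, "C001_R"] <- ifelse(kd, 10, -10) + rnorm(30, 0, 0.1)
  m1 <- rep(FALSE, 10); m1[1] <- TRUE
  expect_equal(ga_fitness(m1, sep, cv_folds = 5, seed = 1), 1)
  # permuting labels must drop fitness to chance (no held-out leakage)
  set.seed(5)
  perm <- tab
  perm$labels <- sample(perm$labels)
  fp <- mean(vapply(1:5, function(s)
    ga_fitness(mask, perm, cv_folds = 5, seed = s), 0))
  expect_lt(abs(fp - 0.5), 0.2)
})

test_that("null features give chance-level fitness at n = 80", {
  tab <- tiny_table(n_kd = 40, n_fc = 40, n_compounds = 12,
                    n_informative = 0, effect_size = 0, seed = 6)
  mask <- rep(TRUE, 12)
  f <- ga_fitness(mask, tab, cv_folds = 5, seed = 2)
  expect_gt(f, 0.5 - 0.15)
  expect_lt(f, 0.5 + 0.15)
})

test_that("evolve is reproducible, monotone under elitism, and bounded", {
  tab <- tiny_table(n_kd = 12, n_fc = 12, n_compounds = 15,
                    n_informative = 3, effect_size = 2.5, seed = 7)
  cfg <- ga_config(population_size = 12, generations = 8, seed = 3)
  r1 <- evolve(tab, cfg)
  r2 <- evolve(tab, cfg)
  expect_identical(r1$best_mask, r2$best_mask)
  expect_identical(r1$trajectory, r2$trajectory)
  # elitism >= 1 makes the best-fitness trajectory non-decreasing
  expect_true(all(diff(r1$trajectory$best) >= 0))
  # generations = 0 evaluates the random initial population only
  r0 <- evolve(tab, ga_config(population_size = 10, generations = 0,
                              seed = 5))
  expect_equal(nrow(r0$trajectory), 1)
  expect_gte(sum(r0$best_mask), 1)
})

test_that("evolve rejects degenerate tables", {
  tab <- tiny_table(n_kd = 10, n_fc = 10, n_compounds = 6, seed = 8)
  one_class <- tab
  one_class$labels <- rep(1L, length(one_class$labels))
  expect_error(evolve(one_class, ga_config(population_size = 4,
                                           generations = 1)),
               "both classes")
})

test_that("selection power grows with effect size on matched seeds", {
  fit_at <- function(d) {
    tab <- tiny_table(n_kd = 15, n_fc = 15, n_compounds = 15,
                      n_informative = 3, effect_size = d, seed = 9)
    res <- evolve(tab, ga_config(population_size = 14, generations = 10,
                                 seed = 4))
    res$best_fitness
  }
  expect_gt(fit_at(2.5), fit_at(0))
})

test_that("GA results serialize to JSON with trajectory and panel", {
  tab <- tiny_table(n_kd = 10, n_fc = 10, n_compounds = 8,
                    n_informative = 2, effect_size = 3, seed = 10)
  res <- evolve(tab, ga_config(population_size = 8, generations = 3,
                               seed = 2))
  js <- jsonlite::fromJSON(ga_to_json(res))
  expect_equal(js$selected, res$selected)
  expect_equal(js$best_fitness, res$best_fitness)
  expect_length(js$trajectory$best, 4)
})
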