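test_that("in-table two-field inputs collapse to the reference score", {
  world <- world_small
  resources <- list(registry = world$eplets, proteins = world$proteins)
  genos <- sample_genotypes(world$freq_table, 8, seed = 201)
  for (k in seq(1, 7, by = 2)) {
    d <- genos[[k]]; r <- genos[[k + 1]]
    for (eng in c("eplet", "pirche2")) {
      res <- imputed_epitope_value(
        phenotype_of(d, level = "twofield"),
        phenotype_of(r, level = "twofield"),
        world$freq_table, world$sermap, engine = eng,
        resources = resources)
      expect_equal(res$n_donor_candidates, 1L)
      expect_equal(res$n_recipient_candidates, 1L)
      ref <- if (eng == "eplet") {
        count_eplet_mismatches(d, r, world$eplets)$count
      } else {
        count_pirche2(d, r, world$proteins)$count
      }
      # weight-1 collapse: exact equality, not merely approximate
      expect_identical(res$expected_value, as.numeric(ref))
    }
  }
})

test_that("two equal-weight recipient candidates scoring 0 and 4 average to 2", {
  # recipient split typing A={A101,A102} where A101 covers A*01/A*02 and
  # A102 is A*03 alone: exactly two equal-frequency candidate genotypes,
  # one carrying A*01:01 (which neutralizes all four donor eplets) and
  # one carrying A*02:01 (which neutralizes none)
  alleles <- c(sprintf("A*%02d:01", 1:4),
               sprintf("%s*%02d:01", rep(c("B", "C", "DRB1", "DQB1"), each = 2),
                       rep(1:2, 4)))
  splits <- c("A101", "A101", "A102", "A103",
              "B101", "B102", "Cw101", "Cw102",
              "DR101", "DR102", "DQ101", "DQ102")
  map <- serology_map(alleles, splits, sub("10", "", splits))
  tab <- toy_table(rbind(c(1, 1, 1, 1, 1), c(2, 1, 1, 1, 1),
                         c(3, 1, 1, 1, 1), c(4, 2, 2, 2, 2)),
                   freq = rep(0.2, 4))
  reg <- setNames(replicate(length(alleles), character(0)), alleles)
  reg[["A*04:01"]] <- c("x1", "x2", "x3", "x4")  # donor eplets
  reg[["A*01:01"]] <- c("x1", "x2", "x3", "x4")  # neutralizing recipient allele
  h4 <- setNames(c("A*04:01", "B*02:01", "C*02:01", "DRB1*02:01",
                   "DQB1*02:01"), hla_loci())
  donor_ph <- phenotype_of(hla_genotype(h4, h4), level = "twofield")
  recip_ph <- hla_phenotype(A = c("A101", "A102"), B = "B101", C = "Cw101",
                            DRB1 = "DR101", DQB1 = "DQ101")
  res <- imputed_epitope_value(donor_ph, recip_ph, tab, map,
                               engine = "eplet",
                               resources = list(registry = reg))
  expect_equal(res$n_donor_candidates, 1L)
  expect_equal(res$n_recipient_candidates, 2L)
  expect_equal(res$expected_value, 2.0, tolerance = 1e-12)
})

test_that("weighted value equals an independent double loop on random couples", {
  world <- world_small
  resources <- list(registry = world$eplets, proteins = world$proteins)
  genos <- sample_genotypes(world$freq_table, 60, seed = 203)
  cache <- new_score_cache()
  memo <- new.env(parent = emptyenv())
  oracle_score <- function(d, r, eng) {
    key <- paste(c(sort(d), "::", sort(r), eng), collapse = "|")
    if (is.null(memo[[key]])) {
      memo[[key]] <- if (eng == "eplet") {
        count_eplet_mismatches(d, r, world$eplets)$count
      } else {
        count_pirche2(d, r, world$proteins)$count
      }
    }
    memo[[key]]
  }
  set.seed(204)
  n_couples <- 200
  for (k in seq_len(n_couples)) {
    d <- genos[[sample.int(60, 1)]]
    r <- genos[[sample.int(60, 1)]]
    eng <- if (k %% 2 == 0) "eplet" else "pirche2"
    d_ph <- degrade(d, world$sermap, "split")
    r_ph <- degrade(r, world$sermap, "split")
    res <- imputed_epitope_value(d_ph, r_ph, world$freq_table, world$sermap,
                                 engine = eng, resources = resources,
                                 cache = cache)
    imp_d <- extrapolate(d_ph, world$freq_table, world$sermap)
    imp_r <- extrapolate(r_ph, world$freq_table, world$sermap)
    expected <- 0
    lo <- Inf; hi <- -Inf; wtot <- 0
    for (i in seq_len(imp_d$n_candidates)) {
      gi <- as.character(candidate_genotype(imp_d, i))
      for (j in seq_len(imp_r$n_candidates)) {
        gj <- as.character(candidate_genotype(imp_r, j))
        s <- oracle_score(gi, gj, eng)
        w <- imp_d$candidates$weight[[i]] * imp_r$candidates$weight[[j]]
        expected <- expected + w * s
        wtot <- wtot + w
        lo <- min(lo, s); hi <- max(hi, s)
      }
    }
    expect_equal(res$expected_value, expected, tolerance = 1e-12)
    # weight conservation and expectation bounds
    expect_equal(wtot, 1, tolerance = 1e-9)
    expect_gte(res$expected_value + 1e-9, lo)
    expect_lte(res$expected_value - 1e-9, hi)
  }
})

test_that("reference scenario bypasses imputation", {
  world <- world_small
  resources <- list(registry = world$eplets, proteins = world$proteins)
  genos <- sample_genotypes(world$freq_table, 2, seed = 205)
  couple <- list(donor = genos[[1]], recipient = genos[[2]])
  for (eng in c("eplet", "pirche2")) {
    res <- scenario_score(couple, world$freq_table, world$sermap,
                          engine = eng, resources = resources,
                          scenario = "reference")
    ref <- if (eng == "eplet") {
      count_eplet_mismatches(genos[[1]], genos[[2]], world$eplets)$count
    } else {
      count_pirche2(genos[[1]], genos[[2]], world$proteins)$count
    }
    expect_identical(res$expected_value, as.numeric(ref))
    expect_equal(res$n_donor_candidates, 1L)
  }
})

test_that("dropping a locus keeps the candidate set nonempty", {
  world <- world_study
  resources <- list(registry = world$eplets)
  genos <- sample_genotypes(world$freq_table, 10, seed = 207)
  for (k in seq(1, 9, by = 2)) {
    couple <- list(donor = genos[[k]], recipient = genos[[k + 1]])
    full <- scenario_score(couple, world$freq_table, world$sermap,
                           engine = "eplet", resources = resources,
                           scenario = "split_both")
    dropc <- scenario_score(couple, world$freq_table, world$sermap,
                            engine = "eplet", resources = resources,
                            scenario = "split_drop_C")
    expect_gte(dropc$n_donor_candidates, 1L)
    expect_gte(dropc$n_recipient_candidates, 1L)
    # dropping a constraint cannot shrink the candidate set under the
    # same scheme
    if (full$scheme_donor == dropc$scheme_donor) {
      expect_gte(dropc$n_donor_candidates, full$n_donor_candidates)
    }
  }
})

test_that("a two-field in-table recipient always collapses to one candidate", {
  world <- world_study
  resources <- list(registry = world$eplets)
  genos <- sample_genotypes(world$freq_table, 6, seed = 209)
  for (k in seq(1, 5, by = 2)) {
    couple <- list(donor = genos[[k]], recipient = genos[[k + 1]])
    res <- scenario_score(couple, world$freq_table, world$sermap,
                          engine = "eplet", resources = resources,
                          scenario = "twofield_recipient_split_donor")
    expect_equal(res$n_recipient_candidates, 1L)
  }
})

test_that("unimputable couples raise a typed condition naming the side", {
  tab <- toy_table(rbind(rep(1, 5), rep(2, 5)))
  map <- toy_map()
  good <- toy_split_phenotype(A = 1, B = 1, C = 1, DRB1 = 1, DQB1 = 1)
  bad <- toy_split_phenotype(A = 5, B = 1, C = 1, DRB1 = 1, DQB1 = 1)
  err <- tryCatch(
    imputed_epitope_value(bad, good, tab, map, engine = "eplet",
                          resources = list(registry = list())),
    epimatch_unimputable = function(e) e)
  expect_true(is_unimputable(err))
  expect_equal(err$side, "donor")
  err2 <- tryCatch(
    imputed_epitope_value(good, bad, tab, map, engine = "eplet",
                          resources = list(registry = list())),
    epimatch_unimputable = function(e) e)
  expect_equal(err2$side, "recipient")
})

test_that("the score cache returns identical results", {
  world <- world_small
  resources <- list(registry = world$eplets, proteins = world$proteins)
  genos <- sample_genotypes(world$freq_table, 2, seed = 211)
  ph_d <- degrade(genos[[1]], world$sermap, "split")
  ph_r <- degrade(genos[[2]], world$sermap, "split")
  cache <- new_score_cache()
  r1 <- imputed_epitope_value(ph_d, ph_r, world$freq_table, world$sermap,
                              engine = "pirche2", resources = resources,
                              cache = cache)
  r2 <- imputed_epitope_value(ph_d, ph_r, world$freq_table, world$sermap,
                              engine = "pirche2", resources = resources,
                              cache = cache)
  r3 <- imputed_epitope_value(ph_d, ph_r, world$freq_table, world$sermap,
                              engine = "pirche2", resources = resources)
  expect_identical(r1$expected_value, r2$expected_value)
  expect_equal(r1$expected_value, r3$expected_value, tolerance = 1e-12)
})
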