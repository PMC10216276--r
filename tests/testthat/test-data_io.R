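# Fixture generation, table loading/validation, and the CSV round trip.

test_that("pair_count multiplies drug and cell panel sizes", {
  expect_equal(pair_count(223, 948), 211404)
  expect_equal(pair_count(1, 1), 1)
  expect_equal(pair_count(10, 7), 70)
})

test_that("generate_fixtures produces a valid cross-product bundle", {
  b <- generate_fixtures(5, 10, seed = 7)
  expect_s3_class(b, "dataset_bundle")
  expect_length(b$drugs, 5)
  expect_equal(nrow(b$cells), 10)
  expect_equal(nrow(b$responses), 50)
  expect_true(all(b$responses$ic50_raw > 0))
  expect_true(all(b$responses$ic50_norm > 0 & b$responses$ic50_norm < 1))
  expect_true(all(b$cells %in% c(0L, 1L)))
  expect_equal(anyDuplicated(b$responses[, c("drug_id", "cell_id")]), 0L)
  expect_setequal(unique(b$responses$drug_id), names(b$drugs))
  expect_error(generate_fixtures(10000, 2, seed = 1), "pool")
})

test_that("fixture generation is a pure function of its arguments", {
  b1 <- generate_fixtures(4, 6, seed = 99, noise_sd = 0.2)
  b2 <- generate_fixtures(4, 6, seed = 99, noise_sd = 0.2)
  expect_identical(b1$drugs, b2$drugs)
  expect_identical(b1$cells, b2$cells)
  expect_identical(b1$responses, b2$responses)
  b3 <- generate_fixtures(4, 6, seed = 100, noise_sd = 0.2)
  expect_false(identical(b1$responses$ic50_raw, b3$responses$ic50_raw))
})

test_that("noiseless fixtures reproduce the planted response formula", {
  b <- generate_fixtures(6, 12, seed = 31, noise_sd = 0)
  # independent recomputation of the planted signal
  n_heavy <- vapply(b$graphs, function(g) g$n_atoms, numeric(1))
  z_drug <- (n_heavy - mean(n_heavy)) / sd(n_heavy)
  ones20 <- rowSums(b$cells[, 1:20])
  z_cell <- (ones20 - mean(ones20)) / sd(ones20)
  expected <- exp(1.5 * z_cell[b$responses$cell_id] +
                    1.0 * z_drug[b$responses$drug_id])
  expect_equal(b$responses$ic50_raw, unname(expected), tolerance = 1e-12)
})

test_that("bundle CSV round trip preserves records exactly", {
  b <- generate_fixtures(3, 5, seed = 17)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  b2 <- load_bundle(file.path(dir, "drugs.csv"), file.path(dir, "cells.csv"),
                    file.path(dir, "responses.csv"))
  expect_identical(unname(b2$drugs), unname(b$drugs))
  expect_equal(unname(b2$cells), unname(b$cells))
  expect_equal(b2$responses$ic50_raw, b$responses$ic50_raw)  # exact doubles
  expect_equal(b2$responses$drug_id, b$responses$drug_id)
  expect_equal(b2$responses$cell_id, b$responses$cell_id)
})

test_that("load_bundle validates references, positivity and duplicates", {
  b <- generate_fixtures(3, 4, seed = 23)
  dir <- withr::local_tempdir()
  paths <- write_bundle(b, dir)
  dcsv <- file.path(dir, "drugs.csv")
  ccsv <- file.path(dir, "cells.csv")
  rcsv <- file.path(dir, "responses.csv")

  # cross-product toy: 3 drugs x 4 cells -> 12 responses
  ok <- load_bundle(dcsv, ccsv, rcsv)
  expect_equal(nrow(ok$responses), 12)

  # unknown drug reference, named by row
  resp <- utils::read.csv(rcsv, stringsAsFactors = FALSE)
  bad <- resp
  bad$drug_id[3] <- "no_such_drug"
  f <- file.path(dir, "bad1.csv"); utils::write.csv(bad, f, row.names = FALSE)
  expect_error(load_bundle(dcsv, ccsv, f), "row 3.*no_such_drug")

  # non-positive IC50 rejected citing positivity
  bad2 <- resp
  bad2$ic50[2] <- 0
  f2 <- file.path(dir, "bad2.csv"); utils::write.csv(bad2, f2, row.names = FALSE)
  expect_error(load_bundle(dcsv, ccsv, f2), "positive")

  # duplicated (drug, cell) pair
  bad3 <- rbind(resp, resp[1, ])
  f3 <- file.path(dir, "bad3.csv"); utils::write.csv(bad3, f3, row.names = FALSE)
  expect_error(load_bundle(dcsv, ccsv, f3), "duplicates")

  # missing column
  bad4 <- resp[, c("drug_id", "cell_id")]
  f4 <- file.path(dir, "bad4.csv"); utils::write.csv(bad4, f4, row.names = FALSE)
  expect_error(load_bundle(dcsv, ccsv, f4), "missing column")
})

test_that("a trained hybrid model beats the target variance on noiseless fixtures", {
  b <- generate_fixtures(5, 40, seed = 47, noise_sd = 0)  # 200 pairs
  target_var <- stats::var(b$responses$ic50_norm)
  cfg <- train_config(n_train = 160L, n_test = 40L, epochs = 20L,
                      batch_size = 64L, seed = 47L, variant = "hybrid",
                      eval_every = 20L)
  sp <- split_dataset(b$responses, cfg)
  m <- hqdr_model("hybrid", seed = 47)
  best <- Inf
  while (m$epochs_trained < 300L && best >= target_var) {
    r <- train_model(m, b, sp$train, sp$test, cfg)
    m <- r$model
    best <- min(best, r$final_test_mse)
  }
  # beating the variance of the targets means the model explains real
  # signal, not just the mean response
  expect_lt(best, target_var)
})

test_that("column remapping supports differently-headed exports", {
  b <- generate_fixtures(2, 3, seed = 29)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  resp <- utils::read.csv(file.path(dir, "responses.csv"),
                          stringsAsFactors = FALSE)
  names(resp)[names(resp) == "ic50"] <- "LN_IC50_EXP"
  f <- file.path(dir, "renamed.csv")
  utils::write.csv(resp, f, row.names = FALSE)
  b2 <- load_bundle(file.path(dir, "drugs.csv"), file.path(dir, "cells.csv"),
                    f, columns = c(ic50 = "LN_IC50_EXP"))
  expect_equal(b2$responses$ic50_raw, b$responses$ic50_raw)
})
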