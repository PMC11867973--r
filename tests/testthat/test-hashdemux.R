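test_that("CLR transform matches the closed form and sums to zero", {
  m <- Matrix::Matrix(rbind(T1 = c(7, 9, 0), T2 = c(7, 0, 5),
                            T3 = c(7, 2, 8), T4 = c(7, 1, 1)), sparse = TRUE)
  colnames(m) <- paste0("c", 1:3)
  clr <- clr_transform(m, paste0("T", 1:4))
  # equal composition maps to zero
  expect_equal(unname(clr[1, ]), rep(0, 4))
  # per-cell sums vanish identically
  expect_true(all(abs(rowSums(clr)) < 1e-12))
  # two-tag cell (9, 0): +/- ln(10)/2
  m2 <- Matrix::Matrix(rbind(A = 9, B = 0), sparse = TRUE)
  colnames(m2) <- "c1"
  clr2 <- clr_transform(m2, c("A", "B"))
  expect_equal(unname(clr2[1, ]), c(log(10) / 2, -log(10) / 2), tolerance = 1e-10)
  expect_equal(unname(clr2[1, 1]), 1.1513, tolerance = 1e-4)
})

test_that("background NB threshold agrees with CDF-summation oracle", {
  set.seed(7)
  x <- rnbinom(5000, mu = 4, size = 4)
  fit <- plexscreen:::fit_background_nb(x)
  thr <- qnbinom(0.99, size = fit$size, mu = fit$mu)
  expect_equal(thr, oracle_nb_quantile(0.99, fit$mu, fit$size))
  # and with the true parameters the fitted threshold is close
  expect_equal(thr, oracle_nb_quantile(0.99, 4, 4), tolerance = 1)
})

test_that("family classification separates singlets, doublets and negatives", {
  # constructed fixture: 3 tags, clear signal/background structure
  set.seed(11)
  n <- 600
  tags <- paste0("T", 1:3)
  assigned <- sample(1:3, n, replace = TRUE)
  m <- matrix(rnbinom(3 * n, mu = 4, size = 5), 3)
  for (i in seq_len(n)) m[assigned[i], i] <- m[assigned[i], i] + rnbinom(1, mu = 300, size = 10)
  # plant a known doublet and a known negative
  m[, 1] <- c(300, 310, 2); assigned[1] <- NA         # doublet T1+T2
  m[, 2] <- c(1, 2, 0); assigned[2] <- NA             # negative
  dimnames(m) <- list(tags, paste0("c", 1:n))
  call <- classify_family(Matrix::Matrix(m, sparse = TRUE), tags,
                          demux_config(k = 4, seed = 3))
  expect_s3_class(call, "family_call")
  expect_equal(as.character(call$class[1]), "doublet")
  expect_equal(as.character(call$class[2]), "negative")
  idx <- which(!is.na(assigned))
  sing <- call$class[idx] == "singlet"
  expect_gt(mean(call$tag[idx][sing] == tags[assigned[idx]][sing]), 0.999)
  # a cell above exactly one threshold is that tag's singlet
  one <- which(sing)[1]
  expect_identical(call$tag[idx][one], tags[assigned[idx][one]])
  expect_error(classify_family(Matrix::Matrix(m[, 1:2], sparse = TRUE), tags,
                               demux_config(k = 4)),
               class = "plex_validation_error")
})

test_that("raising the positive quantile never increases positive calls", {
  ex <- tiny_experiment()
  fam <- attr(ex$tags, "families")
  qs <- c(0.9, 0.99, 0.999)
  npos <- vapply(qs, function(q) {
    sum(classify_family(ex$tags, fam$row,
                        demux_config(positive_quantile = q, seed = 1))$positive)
  }, 0)
  expect_true(all(diff(npos) <= 0))
})

test_that("dual-family demultiplexing applies the retention rule", {
  pm <- make_plate_map()
  mk_call <- function(cls, tag, fam) {
    structure(list(class = factor(cls, levels = c("negative", "singlet", "doublet")),
                   tag = tag,
                   positive = matrix(FALSE, length(cls), length(fam),
                                     dimnames = list(paste0("c", seq_along(cls)), fam)),
                   fits = NULL, cells = paste0("c", seq_along(cls))),
              class = "family_call")
  }
  rc <- mk_call(c("singlet", "doublet", "singlet", "singlet"),
                c("R2", NA, "R1", "R1"), paste0("R", 1:8))
  cc <- mk_call(c("singlet", "singlet", "negative", "singlet"),
                c("C5", "C5", NA, "C1"), paste0("C", 1:12))
  dm <- demultiplex(rc, cc, pm)
  a <- dm$assignments
  # (R2, C5) -> well B05 and its mapped treatment
  expect_identical(a$status[1], "retained")
  expect_identical(a$well[1], "B05")
  expect_identical(a$drug[1], pm$drug[pm$well == "B05"])
  expect_identical(a$reason[2], "row_not_singlet")
  expect_identical(a$reason[3], "col_not_singlet")
  expect_identical(a$status[4], "retained")
  # partition property: every cell is exactly one of retained/discarded
  expect_equal(dm$summary$n_retained + dm$summary$n_discarded, 4)
  # unknown tag in the calls
  rc2 <- mk_call("singlet", "R2", c(paste0("R", 1:8), "R99"))
  cc2 <- mk_call("singlet", "C5", paste0("C", 1:12))
  expect_error(demultiplex(rc2, cc2, pm), class = "plex_validation_error")
})

test_that("empty input yields an empty result with undefined fraction", {
  pm <- make_plate_map()
  empty <- structure(list(class = factor(character(),
                                         levels = c("negative", "singlet", "doublet")),
                          tag = character(),
                          positive = matrix(FALSE, 0, 8,
                                            dimnames = list(NULL, paste0("R", 1:8))),
                          fits = NULL, cells = character()),
                     class = "family_call")
  emptyc <- empty
  colnames(emptyc$positive) <- paste0("C", 1:8)
  emptyc$positive <- emptyc$positive[, 0, drop = FALSE]
  dm <- demultiplex(empty, emptyc, pm)
  expect_equal(dm$summary$n_cells, 0)
  expect_true(is.na(dm$summary$retained_fraction))
})

test_that("on synthetic data retained cells are essentially never misassigned", {
  ex <- tiny_experiment()
  fam <- attr(ex$tags, "families")
  rc <- classify_family(ex$tags, fam$row, demux_config(seed = 1))
  cc <- classify_family(ex$tags, fam$col, demux_config(seed = 1))
  dm <- demultiplex(rc, cc, ex$plate_maps[[1]])
  a <- dm$assignments
  stopifnot(identical(a$barcode, ex$truth$barcode))
  sing <- ex$truth$class == "singlet"
  wrong <- a$status == "retained" & sing & a$well != ex$truth$well
  expect_lt(sum(wrong) / sum(sing), 0.01)
  # counts partition the input
  expect_equal(dm$summary$n_retained + dm$summary$n_discarded, ncol(ex$tags))
  # truth-class doublets are overwhelmingly discarded
  dbl <- ex$truth$class == "doublet"
  expect_gt(mean(a$status[dbl] == "discarded"), 0.95)
})
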