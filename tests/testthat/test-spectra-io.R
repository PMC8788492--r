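test_that("msalign blocks parse into spectra and malformed input is reported by line", {
  f <- withr::local_tempfile(fileext = ".msalign")
  writeLines(c("BEGIN IONS", "ID=sp1", "SCANS=12",
               "PRECURSOR_MASS=1234.5678",
               "100.5\t10\t1", "210.25 20 1", "350.125\t5\t2",
               "400.0\t1\t1", "900.75\t2\t1", "END IONS"), f)
  sp <- read_msalign(f)
  expect_length(sp, 1)
  expect_identical(sp[[1]]$id, "sp1")
  expect_equal(nrow(sp[[1]]$peaks), 5)
  expect_equal(sp[[1]]$precursor_mass, 1234.5678)
  expect_identical(sp[[1]]$extra[["SCANS"]], "12")
  expect_true(!is.unsorted(sp[[1]]$peaks$mass))

  dup <- withr::local_tempfile()
  writeLines(c("BEGIN IONS", "ID=a", "10.0\t1\t1", "END IONS",
               "BEGIN IONS", "ID=a", "20.0\t1\t1", "END IONS"), dup)
  expect_error(read_msalign(dup), "duplicate spectrum id")

  bad <- withr::local_tempfile()
  writeLines(c("BEGIN IONS", "ID=a", "10.0\tx\t1", "END IONS"), bad)
  expect_error(read_msalign(bad), ":3:")

  open_ended <- withr::local_tempfile()
  writeLines(c("BEGIN IONS", "ID=a", "10.0\t1\t1"), open_ended)
  expect_error(read_msalign(open_ended), "no END IONS")

  empty <- withr::local_tempfile()
  writeLines(character(), empty)
  expect_identical(read_msalign(empty), list())
})

test_that("msalign round trip preserves spectra within formatting precision", {
  set.seed(11)
  spectra <- lapply(1:4, function(i)
    random_spectrum(sample(3:30, 1), id = sprintf("sp%d", i),
                    precursor = if (i %% 2) runif(1, 500, 3000) else NA))
  f <- withr::local_tempfile(fileext = ".msalign")
  write_msalign(spectra, f)
  back <- read_msalign(f)
  expect_length(back, 4)
  for (i in 1:4) {
    expect_identical(back[[i]]$id, spectra[[i]]$id)
    expect_equal(back[[i]]$peaks$mass, spectra[[i]]$peaks$mass,
                 tolerance = 1e-6)
    expect_equal(back[[i]]$peaks$intensity, spectra[[i]]$peaks$intensity,
                 tolerance = 1e-6)
    expect_equal(back[[i]]$precursor_mass, spectra[[i]]$precursor_mass,
                 tolerance = 1e-6)
  }
  # writing an empty list yields an empty, re-readable file
  f2 <- withr::local_tempfile()
  write_msalign(list(), f2)
  expect_identical(read_msalign(f2), list())
})

test_that("plain TSV peak lists load with headers honoured", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# ID=tsv1", "# PRECURSOR_MASS=900.5",
               "100.25\t4", "200.5\t7"), f)
  sp <- read_peaks_tsv(f)
  expect_identical(sp$id, "tsv1")
  expect_equal(sp$precursor_mass, 900.5)
  expect_equal(sp$peaks$mass, c(100.25, 200.5))
})

test_that("reflect_peaks mirrors peaks against the precursor mass", {
  sp <- deconv_spectrum("r", 100, 5, precursor_mass = 700)
  refl <- reflect_peaks(sp)
  expect_equal(refl$peaks$mass, c(100, 600))
  expect_equal(refl$peaks$intensity, c(5, 5))

  # a theoretical b ladder reflects onto the y neutral ladder
  pep <- "AVTDPVLSG"
  spb <- theoretical_spectrum(pep, "b", id = "b")
  spy <- theoretical_spectrum(pep, "y", id = "y")
  refl <- reflect_peaks(spb)
  expect_true(all(vapply(spy$peaks$mass, function(m)
    any(abs(refl$peaks$mass - m) < 1e-9), logical(1))))

  # peak at exactly M/2 reflects onto itself; merging collapses it
  half <- deconv_spectrum("h", 350, 2, precursor_mass = 700)
  merged <- merge_peaks(reflect_peaks(half), 0.004)
  expect_equal(nrow(merged$peaks), 1)
  expect_equal(merged$peaks$mass, 350)

  expect_error(reflect_peaks(deconv_spectrum("x", 10, 1)), "precursor")
})

test_that("merge_peaks matches brute-force single-linkage clustering", {
  sp <- deconv_spectrum("m", c(100.000, 100.001), c(1, 3))
  expect_equal(nrow(merge_peaks(sp, 0.004)$peaks), 1)
  # intensity-weighted mean
  expect_equal(merge_peaks(sp, 0.004)$peaks$mass,
               (100.000 * 1 + 100.001 * 3) / 4)
  sp2 <- deconv_spectrum("m2", c(100, 200), c(1, 1))
  expect_equal(merge_peaks(sp2, 0.004)$peaks$mass, c(100, 200))

  set.seed(21)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    tol <- runif(1, 0.001, 0.5)
    m <- sort(runif(n, 100, 110))
    sp <- deconv_spectrum("r", m, runif(n, 1, 10))
    got <- merge_peaks(sp, tol)
    # brute-force partition: transitive closure of the within-tol relation
    grp <- seq_len(n)
    repeat {
      new <- grp
      for (a in 1:n) for (b in 1:n) {
        if (abs(m[a] - m[b]) <= tol) new[c(a, b)] <- min(new[a], new[b])
      }
      if (identical(new, grp)) break
      grp <- new
    }
    expect_equal(nrow(got$peaks), length(unique(grp)))
    # idempotence at the same tolerance
    expect_equal(merge_peaks(got, tol)$peaks, got$peaks)
  }
})

test_that("remove_water_loss drops peaks 18.01 Da below a stronger peak", {
  sp <- deconv_spectrum("w", c(481.98944, 500.0), c(2, 10))
  expect_equal(remove_water_loss(sp, 0.02)$peaks$mass, 500.0)
  # stronger satellite survives
  sp2 <- deconv_spectrum("w2", c(481.98944, 500.0), c(10, 2))
  expect_equal(nrow(remove_water_loss(sp2, 0.02)$peaks), 2)
  sp3 <- deconv_spectrum("w3", c(100, 200, 300), c(1, 2, 3))
  expect_equal(nrow(remove_water_loss(sp3, 0.02)$peaks), 3)

  set.seed(31)
  for (i in 1:15) {
    n <- sample(2:30, 1)
    m <- sort(c(runif(n, 100, 300), runif(3, 100, 300) + WATER))
    int <- runif(length(m), 1, 10)
    sp <- deconv_spectrum("r", m, int)
    got <- remove_water_loss(sp, 0.02)
    drop <- vapply(seq_along(m), function(a)
      any(abs(m - m[a] - WATER) <= 0.02 & int > int[a]), logical(1))
    expect_equal(got$peaks$mass, m[!drop])
    expect_lte(nrow(got$peaks), nrow(sp$peaks))
  }
})

test_that("preprocess_spectrum applies reflection, water loss and merging in order", {
  pep <- "AVTDPVLSG"
  spb <- theoretical_spectrum(pep, "b", id = "b")
  pre <- preprocess_spectrum(spb, reflect = TRUE, merge_tol = 0.004)
  spy <- theoretical_spectrum(pep, "y", id = "y")
  expect_true(all(vapply(spy$peaks$mass, function(m)
    any(abs(pre$peaks$mass - m) < 1e-6), logical(1))))
  expect_warning(
    preprocess_spectrum(deconv_spectrum("np", 100, 1), reflect = TRUE),
    "reflection skipped")
})
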