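cfg_default <- roh_config()

test_that("bin degrees are exact hom/called ratios with NA for empty bins", {
  B <- cfg_default$bin_size
  calls <- tibble::tibble(
    chrom = "chr1",
    pos = c(seq(0, 9000, by = 1000),               # 10 hom in bin 0
            seq(B, B + 9000, by = 1000)),          # 8 hom + 2 het in bin 1
    hom = c(rep(TRUE, 10), rep(TRUE, 8), FALSE, FALSE)
  ) |> dplyr::arrange(pos)
  prof <- bin_profile(calls, c(chr1 = 4 * B), cfg_default)
  expect_equal(prof$degree[1], 1.0)
  expect_equal(prof$degree[2], 0.8)
  expect_true(all(is.na(prof$degree[3:4])))
  expect_equal(prof$n_sites, c(10L, 10L, 0L, 0L))
  expect_error(bin_profile(calls[c(2, 1), ], c(chr1 = 4 * B), cfg_default),
               "not position-sorted")
})

test_that("bin counting matches a per-site brute-force assigner on random inputs", {
  set.seed(101)
  for (rep in 1:30) {
    chrom_len <- sample(3e5:2e6, 1)
    n <- sample(5:200, 1)
    calls <- tibble::tibble(
      chrom = "chr1",
      pos = sort(sample.int(chrom_len, n) - 1L),
      hom = sample(c(TRUE, FALSE), n, replace = TRUE)
    )
    B <- sample(c(1e5L, 2.5e5L, 4e5L), 1)
    cfg <- roh_config(bin_size = B)
    prof <- bin_profile(calls, c(chr1 = chrom_len), cfg)
    oracle <- oracle_bin_counts(calls$pos, calls$hom, chrom_len, B)
    expect_equal(prof$n_sites, oracle$n)
    expect_equal(prof$n_hom, oracle$h)
  }
})

test_that("smoothing preserves constants, averages windows, and truncates at ends", {
  prof <- tibble::tibble(chrom = "chr1", bin = 0:10,
                         start = 0:10 * 4e5, end = 1:11 * 4e5,
                         n_sites = 10L, n_hom = 9L,
                         degree = rep(0.9, 11))
  class(prof) <- c("roh_profile", class(prof))
  s <- smooth_profile(prof, roh_config())
  expect_equal(s$smoothed, rep(0.9, 11))

  prof$degree <- c(1, 1, 1, 1, 1, 0, 1, 1, 1, 1, 1)
  s <- smooth_profile(prof, roh_config())
  expect_equal(s$smoothed[6], 0.8)        # mean of {1,1,0,1,1}

  s0 <- smooth_profile(prof, roh_config(smooth_halfwidth = 0))
  expect_equal(s0$smoothed, prof$degree)  # identity limit

  # NA degrees contribute nothing; all-NA window stays NA
  prof$degree <- c(NA, 0.6, NA, NA, NA, NA, NA, NA, NA, 0.4, NA)
  s <- smooth_profile(prof, roh_config())
  expect_equal(s$smoothed[1], 0.6)
  expect_true(is.na(s$smoothed[6]))
})

test_that("smoothing matches the brute-force windowed mean on random vectors", {
  set.seed(202)
  for (rep in 1:40) {
    n <- sample(3:40, 1)
    d <- runif(n)
    d[sample(n, sample(0:(n %/% 2), 1))] <- NA
    w <- sample(0:3, 1)
    inc <- sample(c(TRUE, FALSE), 1)
    expect_equal(rohscan:::smooth_vector(d, w, inc), oracle_smooth(d, w, inc))
  }
})

test_that("run extraction is maximal, threshold-inclusive, and NA-breaking", {
  mk_prof <- function(d, B = 4e5) {
    p <- tibble::tibble(chrom = "chr1", bin = seq_along(d) - 1L,
                        start = (seq_along(d) - 1) * B,
                        end = seq_along(d) * B,
                        n_sites = 10L, n_hom = 8L, degree = d, smoothed = d)
    class(p) <- c("roh_profile", class(p))
    p
  }
  # saturated chromosome: one ROH spanning it
  r <- call_rohs(mk_prof(rep(1, 10)), roh_config(), breed = "HW")
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(0, 4e6))
  # all-heterozygous chromosome: none
  expect_equal(nrow(call_rohs(mk_prof(rep(0.35, 10)), roh_config())), 0)
  # boundary: smoothed exactly at the threshold is inside
  r <- call_rohs(mk_prof(c(0.5, 0.8, 0.5)), roh_config(smooth_halfwidth = 0))
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(4e5, 8e5))
  # NA breaks a run
  r <- call_rohs(mk_prof(c(0.9, NA, 0.9)), roh_config(smooth_halfwidth = 0))
  expect_equal(nrow(r), 2)

  set.seed(303)
  for (rep in 1:40) {
    n <- sample(3:40, 1)
    d <- runif(n)
    d[sample(n, sample(0:(n %/% 2), 1))] <- NA
    tau <- runif(1, 0.3, 0.9)
    r <- call_rohs(mk_prof(d), roh_config(degree_threshold = tau,
                                          smooth_halfwidth = 0))
    runs <- oracle_runs(d, tau)
    expect_equal(nrow(r), length(runs))
    if (length(runs) > 0) {
      expect_equal(r$start, vapply(runs, function(x) (x[1] - 1) * 4e5,
                                   numeric(1)))
      expect_equal(r$end, vapply(runs, function(x) x[2] * 4e5, numeric(1)))
    }
  }
})

test_that("ROH length accounting and threshold monotonicity hold", {
  set.seed(404)
  d <- runif(50)
  prof <- tibble::tibble(chrom = "chr1", bin = 0:49, start = 0:49 * 4e5,
                         end = 1:50 * 4e5, n_sites = 10L, n_hom = 8L,
                         degree = d)
  class(prof) <- c("roh_profile", class(prof))
  prof <- smooth_profile(prof, roh_config())
  taus <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  bins_in <- vapply(taus, function(tau) {
    r <- call_rohs(prof, roh_config(degree_threshold = tau))
    # conservation: interval lengths equal bin_size * bins in the run
    expect_equal(r$end - r$start, r$n_bins * 4e5)
    sum(r$n_bins)
  }, numeric(1))
  expect_true(all(diff(bins_in) <= 0))
})

test_that("consensus genotype is the NN-ignoring mode with ties as NN", {
  m <- tibble::tibble(
    site_id = paste0("s", 1:3), chrom = "chr1", pos = c(1L, 2L, 3L),
    ref = "A", alt = "C",
    i1 = c("AA", "AA", "NN"),
    i2 = c("AA", "BB", "NN"),
    i3 = c("AB", "NN", "AB")
  )
  expect_equal(consensus_genotypes(m)$call, c("AA", "NN", "AB"))
  calls <- array_calls(consensus_genotypes(m) |>
                         dplyr::mutate(call = c("AA", "AB", "BB")))
  expect_equal(calls$hom, c(TRUE, FALSE, TRUE))
})

test_that("specific-ROH labels match the quadratic overlap oracle", {
  single <- tibble::tibble(chrom = "chr1", start = c(0, 2e6),
                           end = c(8e5, 28e5), breed = "HW",
                           platform = "sequencing")
  expect_true(all(specific_rohs(single)$specific))
  dup <- dplyr::bind_rows(single, single |> dplyr::mutate(breed = "BA"))
  expect_false(any(specific_rohs(dup)$specific))

  set.seed(505)
  for (rep in 1:30) {
    n <- sample(4:25, 1)
    starts <- sample.int(100, n) * 4e5
    rohs <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = starts,
      end = starts + sample.int(8, n, replace = TRUE) * 4e5,
      breed = sample(c("HW", "BA", "HO"), n, replace = TRUE),
      platform = sample(c("sequencing", "array"), n, replace = TRUE)
    )
    expect_equal(specific_rohs(rohs)$specific, oracle_specific(rohs))
  }
  # sROH partition: specific + overlapped = total
  rohs <- tibble::tibble(chrom = "chr1", start = c(0, 4e5, 4e6),
                         end = c(8e5, 12e5, 48e5),
                         breed = c("HW", "BA", "HW"),
                         platform = "sequencing")
  lab <- specific_rohs(rohs)
  expect_equal(sum(lab$specific) + sum(!lab$specific), nrow(rohs))
})

test_that("interval intersection matches the brute-force pairwise oracle", {
  a <- tibble::tibble(chrom = "chr1", start = 0, end = 8e5, breed = "HW")
  b <- tibble::tibble(chrom = "chr1", start = 4e5, end = 12e5, breed = "BA")
  got <- common_rohs(a, b)
  expect_equal(c(got$start, got$end), c(4e5, 8e5))
  expect_equal(nrow(common_rohs(a, b |> dplyr::mutate(start = 9e5))), 0)

  set.seed(606)
  for (rep in 1:30) {
    mk <- function() {
      n <- sample(1:15, 1)
      s <- sample.int(80, n) * 4e5
      tibble::tibble(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                     start = s, end = s + sample.int(10, n, replace = TRUE) * 4e5)
    }
    a <- mk(); b <- mk()
    got <- common_rohs(a, b) |>
      dplyr::arrange(chrom, start, end, a_start, b_start)
    want <- oracle_intersections(a, b)
    if (nrow(want) > 0) {
      want <- want |> dplyr::arrange(chrom, start, end, a_start, b_start)
    }
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$a_start, want$a_start)
      expect_equal(got$b_start, want$b_start)
    }
  }
})

test_that("gene-in-ROH overlap includes single-bp partial overlaps", {
  genes <- tibble::tibble(
    gene_id = c("inside", "one_bp", "outside"),
    chrom = "chr1", strand = "+",
    exons = list(tibble::tibble(start = 500000L, end = 510000L),
                 tibble::tibble(start = 799999L, end = 810000L),
                 tibble::tibble(start = 900000L, end = 910000L)),
    cds = list(tibble::tibble(start = integer(0), end = integer(0)),
               tibble::tibble(start = integer(0), end = integer(0)),
               tibble::tibble(start = integer(0), end = integer(0)))
  )
  rohs <- tibble::tibble(chrom = "chr1", start = 400000, end = 800000,
                         breed = "HW", platform = "sequencing")
  hit <- genes_in_rohs(rohs, genes)
  expect_setequal(hit$gene_id, c("inside", "one_bp"))

  set.seed(707)
  for (rep in 1:20) {
    n_g <- sample(1:10, 1)
    gs <- sample.int(50, n_g) * 1e5
    genes_r <- tibble::tibble(
      gene_id = paste0("g", seq_len(n_g)), chrom = "chr1", strand = "+",
      exons = lapply(gs, function(s) tibble::tibble(start = as.integer(s),
                                                    end = as.integer(s + 5e4))),
      cds = rep(list(tibble::tibble(start = integer(0), end = integer(0))),
                n_g)
    )
    n_r <- sample(1:6, 1)
    rs <- sample.int(12, n_r) * 4e5
    rohs_r <- tibble::tibble(chrom = "chr1", start = rs, end = rs + 4e5,
                             breed = "HW", platform = "sequencing")
    got <- genes_in_rohs(rohs_r, genes_r)
    want <- 0L
    for (i in seq_len(n_r)) {
      for (j in seq_len(n_g)) {
        if (max(rohs_r$start[i], gs[j]) < min(rohs_r$end[i], gs[j] + 5e4)) {
          want <- want + 1L
        }
      }
    }
    expect_equal(nrow(got), want)
  }
})

test_that("an error-free array mirror reproduces the sequencing ROHs", {
  ref <- generate_reference(1, 4e6, 4, seed = 51)
  tracts <- edge_tracts("HW")
  plan <- sim_plan(breeds = c(HW = 1L), planted_rohs = tracts,
                   array_site_frac = 1, array_error_rate = 0, seed = 51)
  cs <- simulate_callsets(ref, plan)
  cfg <- roh_config()
  rohs_seq <- call_rohs(
    smooth_profile(bin_profile(genotype_calls(cs$variants), ref$lengths, cfg)),
    cfg, breed = "HW", platform = "sequencing")
  arr <- derive_array_matrix(cs, plan)
  cons <- consensus_genotypes(arr$matrix)
  rohs_arr <- call_rohs(
    smooth_profile(bin_profile(array_calls(cons), ref$lengths, cfg)),
    cfg, breed = "HW", platform = "array")
  expect_gt(nrow(rohs_seq), 0)
  common <- common_rohs(rohs_seq, rohs_arr)
  # every sequencing ROH is fully covered by the cross-platform intersection
  for (i in seq_len(nrow(rohs_seq))) {
    cv <- common |> dplyr::filter(a_start == rohs_seq$start[i])
    expect_equal(sum(cv$end - cv$start), rohs_seq$end[i] - rohs_seq$start[i])
  }
})
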