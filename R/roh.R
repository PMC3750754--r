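# ROH detection by fixed-width binning of the homozygosity degree, neighbor
# smoothing, and thresholding, plus the set algebra on the resulting
# intervals: breed-specific ROHs, cross-platform/cross-breed intersections,
# consensus array genotypes, and gene overlap.

#' ROH caller configuration
#'
#' @param bin_size Bin width in bp; also the minimum ROH size, since a ROH is
#'   a run of at least one whole bin (default 400,000).
#' @param degree_threshold Smoothed homozygosity degree at or above which a
#'   bin belongs to a ROH (default 0.8, i.e. up to 20% heterozygous calls
#'   allowed per bin).
#' @param smooth_halfwidth Number of neighbor bins averaged on each side of
#'   the center (default 2, a 5-bin mean).
#' @param min_sites_per_bin Bins with fewer called sites get an undefined
#'   degree, which breaks runs (default 1).
#' @param include_center Whether the smoothing window includes the center bin
#'   (default `TRUE`); `FALSE` averages the neighbors only.
#' @return A list of class `roh_config`.
#' @export
roh_config <- function(bin_size = 400000L, degree_threshold = 0.8,
                       smooth_halfwidth = 2L, min_sites_per_bin = 1L,
                       include_center = TRUE) {
  if (bin_size <= 0) abort("bin_size must be positive")
  if (degree_threshold <= 0 || degree_threshold > 1) {
    abort("degree_threshold must lie in (0, 1]")
  }
  if (smooth_halfwidth < 0) abort("smooth_halfwidth must be >= 0")
  if (min_sites_per_bin < 1) abort("min_sites_per_bin must be >= 1")
  structure(list(bin_size = as.integer(bin_size),
                 degree_threshold = degree_threshold,
                 smooth_halfwidth = as.integer(smooth_halfwidth),
                 min_sites_per_bin = as.integer(min_sites_per_bin),
                 include_center = isTRUE(include_center)),
            class = "roh_config")
}

#' Extract hom/het calls from a variants tibble
#'
#' Missing genotypes are excluded; zygosity is judged from the allele index
#' pair (homozygous iff both indices are equal, including hom-ref).
#'
#' @param variants Variants tibble with `chrom`, `pos`, `gt1`, `gt2`.
#' @return Tibble `chrom`, `pos`, `hom` sorted by position, ready for
#'   [bin_profile()].
#' @export
genotype_calls <- function(variants) {
  stopifnot_cols(variants, c("chrom", "pos", "gt1", "gt2"), "variants")
  variants |>
    filter(!is.na(gt1), !is.na(gt2)) |>
    mutate(hom = gt1 == gt2) |>
    select(chrom, pos, hom) |>
    arrange(chrom, pos)
}

#' Bin the homozygosity degree along chromosomes
#'
#' Divides every chromosome into fixed-width bins tiling `[0, length)` (the
#' last partial bin included), counts called and homozygous sites per bin,
#' and computes the degree of homozygosity `degree = hom / called`. Bins with
#' fewer than `min_sites_per_bin` called sites get `NA` degree.
#'
#' @param calls Tibble `chrom`, `pos`, `hom` (see [genotype_calls()]); must
#'   be position-sorted within each chromosome.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param config A [roh_config()].
#' @return Tibble of class `roh_profile`: `chrom`, `bin`, `start`, `end`,
#'   `n_sites`, `n_hom`, `degree` (plus `smoothed` after
#'   [smooth_profile()]).
#' @export
bin_profile <- function(calls, chrom_lengths, config = roh_config()) {
  stopifnot_cols(calls, c("chrom", "pos", "hom"), "calls")
  B <- config$bin_size
  profiles <- lapply(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    cc <- calls[calls$chrom == cn, , drop = FALSE]
    if (nrow(cc) > 1 && is.unsorted(cc$pos)) {
      abort(sprintf("calls on %s are not position-sorted", cn))
    }
    if (nrow(cc) > 0 && (min(cc$pos) < 0 || max(cc$pos) >= len)) {
      abort(sprintf("call position outside chromosome %s", cn))
    }
    n_bins <- as.integer(ceiling(len / B))
    idx <- cc$pos %/% B + 1L
    n_sites <- tabulate(idx, nbins = n_bins)
    n_hom <- tabulate(idx[cc$hom], nbins = n_bins)
    degree <- if_else(n_sites >= config$min_sites_per_bin,
                      n_hom / pmax(n_sites, 1L), NA_real_)
    tibble(chrom = cn, bin = seq_len(n_bins) - 1L,
           start = (seq_len(n_bins) - 1L) * B,
           end = pmin(seq_len(n_bins) * B, as.integer(len)),
           n_sites = n_sites, n_hom = n_hom, degree = degree)
  })
  out <- bind_rows(profiles)
  class(out) <- c("roh_profile", class(out))
  attr(out, "config") <- config
  out
}

#' Smooth the binned homozygosity degree
#'
#' Moving average over the window of `smooth_halfwidth` bins on each side
#' (center bin included by default). Bins with undefined degree contribute
#' nothing; the window is truncated at chromosome ends; the smoothed value is
#' `NA` iff no defined degree falls in the window.
#'
#' @param profile A [bin_profile()] result.
#' @param config A [roh_config()] (defaults to the one stored on `profile`).
#' @return The profile with a `smoothed` column.
#' @export
smooth_profile <- function(profile, config = attr(profile, "config")) {
  config <- config %||% roh_config()
  w <- config$smooth_halfwidth
  out <- profile |>
    group_by(chrom) |>
    mutate(smoothed = smooth_vector(degree, w, config$include_center)) |>
    ungroup()
  class(out) <- c("roh_profile", class(out)[class(out) != "roh_profile"])
  attr(out, "config") <- config
  out
}

smooth_vector <- function(d, w, include_center = TRUE) {
  n <- length(d)
  vapply(seq_len(n), function(i) {
    js <- max(1L, i - w):min(n, i + w)
    if (!include_center) js <- js[js != i]
    vals <- d[js]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) NA_real_ else mean(vals)
  }, numeric(1))
}

#' Call ROHs from a smoothed bin profile
#'
#' Maximal runs of consecutive bins whose smoothed degree meets the threshold
#' (ties included; an `NA` smoothed degree breaks a run) become intervals
#' spanning whole bins, so every ROH is at least one bin wide.
#'
#' @param profile A smoothed [bin_profile()] (run [smooth_profile()] first;
#'   it is applied automatically when the `smoothed` column is absent).
#' @param config A [roh_config()].
#' @param breed,platform Provenance labels attached to each interval.
#' @return Tibble: `chrom`, `start`, `end`, `breed`, `platform`, `n_bins`,
#'   `mean_degree` (mean smoothed degree over the run).
#' @export
call_rohs <- function(profile, config = attr(profile, "config"),
                      breed = "unknown", platform = "sequencing") {
  config <- config %||% roh_config()
  if (!"smoothed" %in% names(profile)) {
    profile <- smooth_profile(profile, config)
  }
  tau <- config$degree_threshold
  out <- profile |>
    group_by(chrom) |>
    dplyr::group_modify(function(df, key) {
      ok <- !is.na(df$smoothed) & df$smoothed >= tau
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      if (length(runs) == 0) {
        return(tibble(start = integer(0), end = integer(0),
                      n_bins = integer(0), mean_degree = numeric(0)))
      }
      tibble(
        start = df$start[starts[runs]],
        end = df$end[ends[runs]],
        n_bins = r$lengths[runs],
        mean_degree = vapply(runs, function(k) {
          mean(df$smoothed[starts[k]:ends[k]])
        }, numeric(1))
      )
    }) |>
    ungroup() |>
    mutate(breed = breed, platform = platform) |>
    select(chrom, start, end, breed, platform, n_bins, mean_degree)
  out
}

#' Consensus genotype per array site within a breed
#'
#' The modal call among AA/AB/BB across individuals, ignoring NN; a tie
#' yields NN (deterministic, conservative), and a site where every individual
#' is NN stays NN.
#'
#' @param matrix Array matrix tibble (see [derive_array_matrix()] /
#'   [read_array()]).
#' @param samples Character vector of the individual columns to use
#'   (default: all).
#' @return Tibble `site_id`, `chrom`, `pos`, `ref`, `alt`, `call`.
#' @export
consensus_genotypes <- function(matrix, samples = NULL) {
  meta <- c("site_id", "chrom", "pos", "ref", "alt")
  stopifnot_cols(matrix, meta, "array matrix")
  samples <- samples %||% setdiff(names(matrix), meta)
  if (length(samples) == 0) abort("no sample columns selected")
  calls <- as.matrix(matrix[, samples, drop = FALSE])
  consensus <- apply(calls, 1L, function(row) {
    row <- row[row != "NN"]
    if (length(row) == 0) return("NN")
    tab <- table(row)
    top <- tab[tab == max(tab)]
    if (length(top) > 1) "NN" else names(top)
  })
  matrix |>
    select(all_of(meta)) |>
    mutate(call = unname(consensus))
}

#' Convert array calls to hom/het calls for binning
#'
#' @param consensus Output of [consensus_genotypes()] (or any tibble with
#'   `chrom`, `pos`, `call`); NN calls are dropped.
#' @return Tibble `chrom`, `pos`, `hom` for [bin_profile()].
#' @export
array_calls <- function(consensus) {
  stopifnot_cols(consensus, c("chrom", "pos", "call"), "consensus calls")
  consensus |>
    filter(call != "NN") |>
    mutate(hom = call %in% c("AA", "BB")) |>
    select(chrom, pos, hom) |>
    arrange(chrom, pos)
}

#' Label breed-specific ROHs
#'
#' A ROH is specific iff it overlaps (by at least 1 bp) no ROH of any other
#' breed on the same platform.
#'
#' @param rohs ROH tibble covering all breeds of one or more platforms.
#' @return `rohs` with a logical `specific` column.
#' @export
specific_rohs <- function(rohs) {
  stopifnot_cols(rohs, c("chrom", "start", "end", "breed", "platform"), "rohs")
  if (nrow(rohs) == 0) return(rohs |> mutate(specific = logical(0)))
  gr <- intervals_to_granges(rohs)
  hits <- GenomicRanges::findOverlaps(gr, gr)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  cross <- q != s & rohs$breed[q] != rohs$breed[s] &
    rohs$platform[q] == rohs$platform[s]
  rohs |> mutate(specific = !seq_len(nrow(rohs)) %in% q[cross])
}

#' Intersect two ROH sets
#'
#' Pairwise interval intersections of at least 1 bp, reported as the
#' intersection coordinates with both parent intervals referenced. Used both
#' for cross-platform common ROHs within a breed and for cross-breed
#' overlapping ROHs.
#'
#' @param rohs_a,rohs_b ROH tibbles (`chrom`, `start`, `end`, plus any
#'   provenance columns, carried through with `a_`/`b_` prefixes).
#' @return Tibble: `chrom`, `start`, `end` of each intersection plus
#'   `a_start`, `a_end`, `b_start`, `b_end` and prefixed provenance columns.
#' @export
common_rohs <- function(rohs_a, rohs_b) {
  for (df in list(rohs_a, rohs_b)) {
    stopifnot_cols(df, c("chrom", "start", "end"), "rohs")
  }
  if (nrow(rohs_a) == 0 || nrow(rohs_b) == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  a_start = integer(0), a_end = integer(0),
                  b_start = integer(0), b_end = integer(0)))
  }
  gr_a <- intervals_to_granges(rohs_a)
  gr_b <- intervals_to_granges(rohs_b)
  # sets on entirely different chromosomes are a legitimate empty overlap
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_a, gr_b))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  base <- tibble(
    chrom = rohs_a$chrom[q],
    start = pmax(rohs_a$start[q], rohs_b$start[s]),
    end = pmin(rohs_a$end[q], rohs_b$end[s]),
    a_start = rohs_a$start[q], a_end = rohs_a$end[q],
    b_start = rohs_b$start[s], b_end = rohs_b$end[s]
  )
  extra_a <- setdiff(names(rohs_a), c("chrom", "start", "end"))
  extra_b <- setdiff(names(rohs_b), c("chrom", "start", "end"))
  for (cl in extra_a) base[[paste0("a_", cl)]] <- rohs_a[[cl]][q]
  for (cl in extra_b) base[[paste0("b_", cl)]] <- rohs_b[[cl]][s]
  base
}

#' Genes overlapping ROHs
#'
#' A gene is included iff its genomic span overlaps the ROH partially or
#' completely (at least 1 bp).
#'
#' @param rohs ROH tibble.
#' @param genes Gene table (see [genome_bundle()]).
#' @return Tibble: one row per (ROH, gene) overlap with the ROH columns plus
#'   `gene_id`.
#' @export
genes_in_rohs <- function(rohs, genes) {
  spans <- gene_spans(genes)
  if (nrow(rohs) == 0 || nrow(spans) == 0) {
    return(rohs[0, ] |> mutate(gene_id = character(0)))
  }
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(intervals_to_granges(rohs),
                                intervals_to_granges(spans))
  )
  out <- rohs[S4Vectors::queryHits(hits), ]
  out$gene_id <- spans$gene_id[S4Vectors::subjectHits(hits)]
  out
}

#' Subtract other breeds' ROHs from each ROH (fragment view)
#'
#' Complements [specific_rohs()]: instead of labeling whole intervals, removes
#' every other breed's overlapped portion and returns the remaining
#' fragments, which is how a breed's specific ROH count can exceed its ROH
#' count.
#'
#' @param rohs ROH tibble for all breeds on one platform.
#' @return Tibble of fragments with `chrom`, `start`, `end`, `breed`,
#'   `platform`.
#' @export
subtract_rohs <- function(rohs) {
  stopifnot_cols(rohs, c("chrom", "start", "end", "breed", "platform"), "rohs")
  out <- list()
  for (b in unique(rohs$breed)) {
    for (p in unique(rohs$platform)) {
      own <- rohs |> filter(breed == b, platform == p)
      other <- rohs |> filter(breed != b, platform == p)
      if (nrow(own) == 0) next
      if (nrow(other) == 0) {
        frag <- own |> select(chrom, start, end)
      } else {
        frag <- granges_to_intervals(
          GenomicRanges::setdiff(intervals_to_granges(own),
                                 GenomicRanges::reduce(intervals_to_granges(other)))
        )
      }
      if (nrow(frag) > 0) {
        out[[length(out) + 1L]] <- frag |> mutate(breed = b, platform = p)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  breed = character(0), platform = character(0)))
  }
  bind_rows(out)
}
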