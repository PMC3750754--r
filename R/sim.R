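# Multi-breed diploid genotype simulator with planted homozygous tracts and a
# paired SNP-array mirror. Everything downstream is benchmarked against the
# truth tables this module emits.

#' Build a simulation plan
#'
#' Collects and validates all parameters of the synthetic study design.
#' Defaults emulate a deep-resequencing study of one bull per breed: SNP
#' density of one site per 500 bp, 65% heterozygous genotypes among variant
#' calls outside homozygous tracts with a residual 5% inside, 7.5% of sites
#' being small indels with lengths in -14..+22 bp, 48.8% of sites present in
#' the known-variant catalogue, and ~45x mean read depth.
#'
#' @param breeds Named integer vector: breed name to number of individuals.
#' @param planted_rohs Tibble with columns `breed`, `chrom`, `start`, `end`
#'   (0-based half-open) giving the homozygous tracts to plant per breed.
#' @param snp_rate Expected variant sites per bp.
#' @param het_frac_outside Probability a genotype is heterozygous outside
#'   planted tracts. Non-het genotypes outside tracts are homozygous-alt, so
#'   among variant genotypes the het fraction equals this value.
#' @param het_frac_inside Residual heterozygote probability inside tracts;
#'   non-het genotypes inside split evenly between hom-ref and hom-alt.
#' @param indel_frac Fraction of sites simulated as indels (placed only in
#'   CDS or intergenic sequence so frameshift truth is unambiguous).
#' @param known_frac Fraction of sites entered into the known-variant
#'   catalogue.
#' @param array_site_frac Fraction of SNP sites mirrored onto the array.
#' @param array_error_rate Probability an array genotype is perturbed to one
#'   of the two other genotypes (uniformly).
#' @param depth_mean Mean simulated read depth per site.
#' @param seed Integer seed; fixing it makes all outputs byte-identical.
#' @return A list of class `sim_plan`.
#' @export
sim_plan <- function(breeds = c(HW = 1L, BA = 1L, HO = 1L),
                     planted_rohs = tibble(breed = character(),
                                           chrom = character(),
                                           start = integer(), end = integer()),
                     snp_rate = 1 / 500,
                     het_frac_outside = 0.65,
                     het_frac_inside = 0.05,
                     indel_frac = 0.075,
                     known_frac = 0.488,
                     array_site_frac = 0.01,
                     array_error_rate = 0.04,
                     depth_mean = 45.6,
                     seed = 1L) {
  fracs <- c(het_frac_outside = het_frac_outside,
             het_frac_inside = het_frac_inside, indel_frac = indel_frac,
             known_frac = known_frac, array_site_frac = array_site_frac,
             array_error_rate = array_error_rate)
  if (any(fracs < 0 | fracs > 1)) {
    abort(sprintf("fractions must lie in [0, 1]; offending: %s",
                  paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", ")))
  }
  if (snp_rate <= 0) abort("snp_rate must be positive")
  if (depth_mean <= 0) abort("depth_mean must be positive")
  if (is.null(names(breeds)) || any(names(breeds) == "")) {
    abort("breeds must be a named vector of individual counts")
  }
  planted_rohs <- as_tibble(planted_rohs)
  stopifnot_cols(planted_rohs, c("breed", "chrom", "start", "end"), "planted_rohs")
  if (nrow(planted_rohs) > 0 && any(planted_rohs$end <= planted_rohs$start)) {
    abort("planted tracts must have end > start")
  }
  structure(
    list(breeds = breeds, planted_rohs = planted_rohs, snp_rate = snp_rate,
         het_frac_outside = het_frac_outside, het_frac_inside = het_frac_inside,
         indel_frac = indel_frac, known_frac = known_frac,
         array_site_frac = array_site_frac, array_error_rate = array_error_rate,
         depth_mean = depth_mean, seed = as.integer(seed)),
    class = "sim_plan"
  )
}

INDEL_LENGTHS <- c(-14:-1, 1:22)

#' Simulate per-breed diploid callsets with planted homozygous tracts
#'
#' Draws variant sites along each chromosome at `snp_rate`, assigns each
#' individual a genotype according to tract membership, simulates Poisson read
#' depth with a multinomial ref/alt split (95% major allele for homozygotes,
#' 50/50 expectation for heterozygotes), and attaches a deleteriousness score
#' in \[0,1\] and a known-catalogue flag to every site. A fraction of sites
#' are indels with length drawn uniformly from -14..+22 bp (excluding 0),
#' placed only where the affected bases lie wholly inside one CDS interval or
#' wholly outside all genes.
#'
#' @param bundle A [genome_bundle()].
#' @param plan A [sim_plan()]; planted tracts must lie within chromosomes.
#' @return List with elements:
#'   * `variants`: tibble with one row per breed x individual x site
#'     (`breed`, `sample_id`, `chrom`, `pos`, `ref`, `alt`, `gt1`, `gt2`,
#'     `depth`, `ad` list column `c(ref, alt)`, `score`, `known`, `is_indel`),
#'   * `sites`: tibble of the per-site truth (alleles, score, known flag),
#'   * `truth`: the planted tracts,
#'   * `known_sites`: the known-variant catalogue (`chrom`,`pos`,`ref`,`alt`).
#' @export
simulate_callsets <- function(bundle, plan) {
  stopifnot(inherits(bundle, "genome_bundle"), inherits(plan, "sim_plan"))
  tracts <- plan$planted_rohs
  if (nrow(tracts) > 0) {
    bad <- !tracts$chrom %in% names(bundle$lengths) |
      tracts$start < 0 | tracts$end > bundle$lengths[tracts$chrom]
    if (any(bad)) {
      abort("planted tract outside chromosome bounds",
            class = "rohscan_bounds_error")
    }
    unknown_breed <- setdiff(tracts$breed, names(plan$breeds))
    if (length(unknown_breed) > 0) {
      abort(sprintf("planted tract for unknown breed: %s",
                    paste(unknown_breed, collapse = ", ")))
    }
  }
  set.seed(plan$seed)
  sites <- draw_sites(bundle, plan)
  variants <- draw_genotypes(sites, bundle, plan)
  known_sites <- sites |>
    filter(known) |>
    select(chrom, pos, ref, alt)
  list(variants = variants, sites = sites, truth = tracts,
       known_sites = known_sites)
}

# Per-site truth: positions, alleles, indel status, score, known flag.
draw_sites <- function(bundle, plan) {
  spans <- gene_spans(bundle$genes)
  out <- lapply(names(bundle$sequences), function(cn) {
    len <- bundle$lengths[[cn]]
    n_sites <- rbinom(1L, len, plan$snp_rate)
    if (n_sites == 0) return(NULL)
    pos <- sort(sample.int(len - 40L, n_sites)) - 1L  # keep room for indels
    seqvec <- strsplit(bundle$sequences[[cn]], "")[[1]]
    ref_base <- seqvec[pos + 1L]
    alt_base <- vapply(ref_base, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1), USE.NAMES = FALSE)
    want_indel <- runif(n_sites) < plan$indel_frac
    eligible <- indel_eligible(cn, pos, bundle, spans)
    is_indel <- want_indel & eligible
    ref <- ref_base
    alt <- alt_base
    if (any(is_indel)) {
      ilen <- sample(INDEL_LENGTHS, sum(is_indel), replace = TRUE)
      idx <- which(is_indel)
      for (k in seq_along(idx)) {
        i <- idx[k]
        if (ilen[k] < 0) {  # deletion: REF = anchor + |len| bases, ALT = anchor
          ref[i] <- paste(seqvec[(pos[i] + 1L):(pos[i] + 1L - ilen[k])],
                          collapse = "")
          alt[i] <- ref_base[i]
        } else {            # insertion: REF = anchor, ALT = anchor + len bases
          ref[i] <- ref_base[i]
          alt[i] <- paste0(ref_base[i],
                           paste(sample(c("A", "C", "G", "T"), ilen[k],
                                        replace = TRUE), collapse = ""))
        }
      }
    }
    tibble(chrom = cn, pos = pos, ref = ref, alt = alt, is_indel = is_indel,
           score = round(runif(n_sites), 4),
           known = runif(n_sites) < plan$known_frac)
  })
  bind_rows(out)
}

# A site may carry an indel if the +/-40 bp window around it lies wholly
# inside one CDS interval or wholly outside every gene span.
indel_eligible <- function(cn, pos, bundle, spans) {
  n <- length(pos)
  if (nrow(spans) == 0) return(rep(TRUE, n))
  sp <- spans[spans$chrom == cn, , drop = FALSE]
  if (nrow(sp) == 0) return(rep(TRUE, n))
  lo <- pos; hi <- pos + 40L
  outside <- rep(TRUE, n)
  for (j in seq_len(nrow(sp))) {
    outside <- outside & (hi <= sp$start[j] | lo >= sp$end[j])
  }
  inside_cds <- rep(FALSE, n)
  genes_cn <- bundle$genes[bundle$genes$chrom == cn, , drop = FALSE]
  for (g in seq_len(nrow(genes_cn))) {
    cds <- genes_cn$cds[[g]]
    for (j in seq_len(nrow(cds))) {
      inside_cds <- inside_cds | (lo >= cds$start[j] & hi <= cds$end[j])
    }
  }
  outside | inside_cds
}

# Genotypes, depth and allele depths for every breed x individual x site.
draw_genotypes <- function(sites, bundle, plan) {
  out <- list()
  for (b in names(plan$breeds)) {
    tr <- plan$planted_rohs |> filter(breed == b)
    in_tract <- rep(FALSE, nrow(sites))
    if (nrow(tr) > 0) {
      for (j in seq_len(nrow(tr))) {
        in_tract <- in_tract | (sites$chrom == tr$chrom[j] &
                                  sites$pos >= tr$start[j] &
                                  sites$pos < tr$end[j])
      }
    }
    for (ind in seq_len(plan$breeds[[b]])) {
      n <- nrow(sites)
      u <- runif(n)
      gt1 <- integer(n); gt2 <- integer(n)
      # outside tracts: het w.p. het_frac_outside, else hom-alt
      het_out <- !in_tract & u < plan$het_frac_outside
      homalt_out <- !in_tract & !het_out
      # inside tracts: het w.p. het_frac_inside, else hom (50/50 ref/alt)
      het_in <- in_tract & u < plan$het_frac_inside
      hom_in <- in_tract & !het_in
      homalt_in <- hom_in & runif(n) < 0.5
      gt1[het_out | het_in] <- 0L
      gt2[het_out | het_in] <- 1L
      gt1[homalt_out | homalt_in] <- 1L
      gt2[homalt_out | homalt_in] <- 1L
      depth <- pmax(1L, rpois(n, plan$depth_mean))
      hom <- gt1 == gt2
      major_p <- if_else(hom, 0.95, 0.5)
      major_ad <- rbinom(n, depth, major_p)
      # major allele: alt for carriers of alt/alt or het (het: split 50/50
      # between ref and alt by construction); ref for hom-ref
      alt_ad <- integer(n)
      alt_ad[gt1 == 1L & gt2 == 1L] <- major_ad[gt1 == 1L & gt2 == 1L]
      alt_ad[gt1 != gt2] <- major_ad[gt1 != gt2]
      alt_ad[gt1 == 0L & gt2 == 0L] <- (depth - major_ad)[gt1 == 0L & gt2 == 0L]
      ref_ad <- depth - alt_ad
      out[[length(out) + 1L]] <- tibble(
        breed = b,
        sample_id = sprintf("%s_%02d", b, ind),
        chrom = sites$chrom, pos = sites$pos,
        ref = sites$ref, alt = sites$alt,
        gt1 = gt1, gt2 = gt2,
        depth = depth,
        ad = lapply(seq_len(n), function(i) c(ref_ad[i], alt_ad[i])),
        score = sites$score, known = sites$known,
        is_indel = sites$is_indel
      )
    }
  }
  bind_rows(out)
}

#' Mirror a sequencing callset onto a SNP-array genotype matrix
#'
#' Subsamples a fraction of the SNP sites (indels are never arrayed), codes
#' each individual's genotype as AA/AB/BB with A = reference allele and
#' B = alternate allele (missing genotypes become NN), and perturbs each cell
#' with probability `array_error_rate`, moving the genotype to one of the two
#' other states uniformly. The perturbed cells are returned as truth.
#'
#' @param callsets Result of [simulate_callsets()], or any variants tibble of
#'   the same layout.
#' @param plan The [sim_plan()]; uses `array_site_frac`, `array_error_rate`,
#'   and a stream derived from `seed`.
#' @return List with `matrix` (tibble: `site_id`, `chrom`, `pos`, `ref`,
#'   `alt`, then one AA/AB/BB/NN column per individual) and `perturbed`
#'   (tibble of cells that were changed, with old and new calls).
#' @export
derive_array_matrix <- function(callsets, plan) {
  variants <- if (is.list(callsets) && !is.data.frame(callsets)) {
    callsets$variants
  } else {
    callsets
  }
  if (nrow(variants) == 0) abort("callsets must be non-empty")
  set.seed(plan$seed + 1013L)
  site_tab <- variants |>
    filter(!is_indel) |>
    distinct(chrom, pos, ref, alt) |>
    arrange(chrom, pos)
  keep <- runif(nrow(site_tab)) < plan$array_site_frac
  site_tab <- site_tab[keep, , drop = FALSE]
  if (nrow(site_tab) == 0) {
    abort("array_site_frac left zero array sites; increase it or the SNP rate")
  }
  site_tab <- site_tab |>
    mutate(site_id = sprintf("ARS%06d", row_number()), .before = 1)

  calls <- variants |>
    inner_join(site_tab, by = c("chrom", "pos", "ref", "alt")) |>
    mutate(call = dplyr::case_when(
      is.na(gt1) | is.na(gt2) ~ "NN",
      gt1 == 0L & gt2 == 0L ~ "AA",
      gt1 != gt2 ~ "AB",
      TRUE ~ "BB"
    ))
  flip <- runif(nrow(calls)) < plan$array_error_rate & calls$call != "NN"
  states <- c("AA", "AB", "BB")
  new_call <- calls$call
  if (any(flip)) {
    new_call[flip] <- vapply(calls$call[flip], function(g) {
      sample(setdiff(states, g), 1)
    }, character(1), USE.NAMES = FALSE)
  }
  perturbed <- calls[flip, c("sample_id", "chrom", "pos")] |>
    mutate(old = calls$call[flip], new = new_call[flip])
  calls$call <- new_call
  wide <- calls |>
    select(site_id, sample_id, call) |>
    tidyr::pivot_wider(names_from = sample_id, values_from = call,
                       values_fill = "NN")
  mat <- site_tab |>
    left_join(wide, by = "site_id") |>
    arrange(chrom, pos)
  sample_cols <- setdiff(names(mat), c("site_id", "chrom", "pos", "ref", "alt"))
  mat <- mat |> mutate(across(all_of(sample_cols), ~ tidyr::replace_na(.x, "NN")))
  list(matrix = mat, perturbed = perturbed)
}
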