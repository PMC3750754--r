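# Variant consequence classification against representative gene models, and
# the NS/SS/I (non-synonymous / splice-site / coding-indel) filter chain:
# novelty against a known-variant catalogue, deleteriousness (score < 0.05,
# strict), and breed specificity with read-depth support rules.

CONSEQUENCE_LEVELS <- c("intergenic", "intron", "utr5", "utr3", "splice_site",
                        "synonymous", "missense", "nonsense", "readthrough",
                        "frameshift_indel", "inframe_indel")

NSSI_CATEGORIES <- c("missense", "nonsense", "readthrough", "splice_site",
                     "frameshift_indel", "inframe_indel")

# Severity order used to collapse multiallelic records to one category.
SEVERITY <- c(frameshift_indel = 10, nonsense = 9, readthrough = 8,
              splice_site = 7, missense = 6, inframe_indel = 5,
              synonymous = 4, utr5 = 3, utr3 = 3, intron = 2, intergenic = 1)

#' Classify variants by genic context and coding consequence
#'
#' Assigns every distinct variant site exactly one consequence category per
#' overlapping gene model (variants overlapping no gene are `intergenic`):
#'
#' * SNP in CDS: the affected codon is translated on the coding strand with
#'   the reference versus alternate base; identical amino acid gives
#'   `synonymous`, a gained stop `nonsense`, a lost stop `readthrough`,
#'   anything else `missense`.
#' * Indel overlapping CDS: `frameshift_indel` when the net length change is
#'   not a multiple of 3, else `inframe_indel`.
#' * Variant on the first or last two bases of an intron (the canonical GT/AG
#'   donor/acceptor dinucleotides): `splice_site`, which takes precedence
#'   over `intron` and over UTR; coding categories take precedence over
#'   `splice_site` only when an affected base itself lies in CDS.
#' * Exonic non-coding positions: `utr5`/`utr3` by transcript position
#'   relative to the CDS on the coding strand.
#'
#' Multiallelic records receive the most severe category across their
#' alternate alleles.
#'
#' @param variants Variants tibble (`chrom`, `pos`, `ref`, `alt`; other
#'   columns are ignored). Distinct sites are classified once.
#' @param genes Gene table (see [genome_bundle()]); models violating the gene
#'   invariants raise an error before classification.
#' @param genome A [genome_bundle()] supplying reference sequence for codons.
#' @return Tibble with one row per (site, overlapping gene): `chrom`, `pos`,
#'   `ref`, `alt`, `gene_id` (`NA` for intergenic), `category`.
#' @export
classify_variants <- function(variants, genes, genome) {
  stopifnot_cols(variants, c("chrom", "pos", "ref", "alt"), "variants")
  for (i in seq_len(nrow(genes))) validate_gene_model(genes[i, ])
  sites <- variants |> distinct(chrom, pos, ref, alt)
  spans <- gene_spans(genes)

  if (nrow(spans) == 0 || nrow(sites) == 0) {
    return(sites |> mutate(gene_id = NA_character_, category = "intergenic"))
  }
  # candidate pairing on gene spans (indels padded by their REF length)
  pad <- nchar(sites$ref)
  v_gr <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos + 1L,
                                                  sites$pos + pad))
  g_gr <- intervals_to_granges(spans)
  hits <- GenomicRanges::findOverlaps(v_gr, g_gr)
  pairs <- tibble(v = S4Vectors::queryHits(hits), g = S4Vectors::subjectHits(hits))

  classified <- purrr::pmap(pairs, function(v, g) {
    s <- sites[v, ]
    gene <- genes[genes$gene_id == spans$gene_id[g], ][1, ]
    cats <- vapply(strsplit(s$alt, ",")[[1]], function(a) {
      classify_one(s$chrom, s$pos, s$ref, a, gene, genome)
    }, character(1), USE.NAMES = FALSE)
    cats <- cats[!is.na(cats)]
    if (length(cats) == 0) return(NULL)
    s |> mutate(gene_id = gene$gene_id,
                category = cats[which.max(SEVERITY[cats])])
  }) |> bind_rows()

  hit_v <- unique(pairs$v)
  genic_keys <- if (nrow(classified) > 0) {
    paste(classified$chrom, classified$pos, classified$ref, classified$alt)
  } else character(0)
  inter <- sites |>
    mutate(.key = paste(chrom, pos, ref, alt)) |>
    filter(!.key %in% genic_keys) |>
    select(-".key") |>
    mutate(gene_id = NA_character_, category = "intergenic")
  bind_rows(classified, inter) |> arrange(chrom, pos)
}

# Classify a single (variant, alt allele, gene) triple; NA when the variant's
# affected bases do not touch this gene's span.
classify_one <- function(chrom, pos, ref, alt, gene, genome) {
  if (chrom != gene$chrom) return(NA_character_)
  ex <- gene$exons[[1]]
  span <- c(min(ex$start), max(ex$end))
  is_indel <- nchar(ref) != nchar(alt)
  cds_pos <- gene_cds_positions(gene)       # transcript order
  introns <- gene_introns(gene)
  splice_pos <- if (nrow(introns) > 0) {
    unlist(lapply(seq_len(nrow(introns)), function(j) {
      c(introns$start[j], introns$start[j] + 1L,
        introns$end[j] - 2L, introns$end[j] - 1L)
    }))
  } else integer(0)

  if (!is_indel) {
    if (pos < span[1] || pos >= span[2]) return(NA_character_)
    if (pos %in% cds_pos) return(classify_cds_snp(chrom, pos, ref, alt, gene,
                                                  cds_pos, genome))
    if (pos %in% splice_pos) return("splice_site")
    in_exon <- any(ex$start <= pos & pos < ex$end)
    if (in_exon) return(utr_side(pos, gene))
    return("intron")
  }

  # indel: affected bases are the deleted span (anchored deletions) or the
  # insertion junction between pos and pos+1
  net <- nchar(alt) - nchar(ref)
  if (net < 0) {
    affected <- seq.int(pos + 1L, pos + nchar(ref) - 1L)
    touches <- function(set) any(affected %in% set)
    inside_span <- any(affected >= span[1] & affected < span[2])
  } else {
    junction <- pos + 1L
    touches <- function(set) {
      # insertion interrupts a run iff both flanking bases are in the set
      (junction - 1L) %in% set && junction %in% set
    }
    inside_span <- junction > span[1] && junction < span[2]
    affected <- junction
  }
  if (!inside_span) return(NA_character_)
  if (touches(cds_pos)) {
    return(if (net %% 3 != 0) "frameshift_indel" else "inframe_indel")
  }
  if (touches(splice_pos)) return("splice_site")
  exon_set <- unlist(lapply(seq_len(nrow(ex)), function(j) {
    seq.int(ex$start[j], ex$end[j] - 1L)
  }))
  if (touches(exon_set)) return(utr_side(min(affected), gene))
  "intron"
}

classify_cds_snp <- function(chrom, pos, ref, alt, gene, cds_pos, genome) {
  idx <- match(pos, cds_pos)                 # 1-based CDS coordinate
  codon_i <- (idx - 1L) %/% 3L
  within <- (idx - 1L) %% 3L
  codon_gpos <- cds_pos[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
  seqchr <- genome$sequences[[chrom]]
  bases <- vapply(codon_gpos, function(p) substr(seqchr, p + 1L, p + 1L),
                  character(1))
  if (gene$strand == "-") bases <- complement_base(bases)
  ref_codon <- bases
  # trust the VCF REF/ALT at the variant base itself
  ref_codon[within + 1L] <- if (gene$strand == "-") complement_base(ref) else ref
  alt_codon <- ref_codon
  alt_codon[within + 1L] <- if (gene$strand == "-") complement_base(alt) else alt
  ref_aa <- translate_codons(paste(ref_codon, collapse = ""))
  alt_aa <- translate_codons(paste(alt_codon, collapse = ""))
  if (ref_aa == alt_aa) return("synonymous")
  if (alt_aa == "*") return("nonsense")
  if (ref_aa == "*") return("readthrough")
  "missense"
}

# 5' or 3' UTR by transcript coordinate relative to the CDS.
utr_side <- function(pos, gene) {
  tx <- gene_tx_positions(gene)
  cds_pos <- gene_cds_positions(gene)
  if (length(cds_pos) == 0) return("utr5")
  t <- match(pos, tx)
  t_cds_start <- match(cds_pos[1], tx)
  if (is.na(t)) return("intron")
  if (t < t_cds_start) "utr5" else "utr3"
}

#' Build the NS/SS/I record set
#'
#' Keeps the (variant, gene) pairs whose category is missense, nonsense,
#' readthrough, splice-site, frameshift or in-frame indel; flags novelty
#' (absence from the known catalogue), deleteriousness (score strictly below
#' `damaging_cutoff`), and collects the breeds whose samples carry a
#' non-reference genotype at the site.
#'
#' @param classified Output of [classify_variants()].
#' @param variants The multi-breed variants tibble (needs `breed`, `gt1`,
#'   `gt2`, and `score` when damaging flags are wanted).
#' @param known_sites Optional known-variant catalogue (`chrom`, `pos`,
#'   `ref`, `alt`); when `NULL`, a logical `known` column on `variants` is
#'   used if present, else everything is novel.
#' @param damaging_cutoff Strict upper bound on the deleteriousness score for
#'   the damaging flag (default 0.05; a score of exactly 0.05 is not
#'   damaging).
#' @return Tibble: `chrom`, `pos`, `ref`, `alt`, `gene_id`, `category`,
#'   `novel`, `damaging`, `breeds_present` (list column), `specific_to`
#'   (`NA`, see [specific_nssi()]).
#' @export
build_nssi <- function(classified, variants, known_sites = NULL,
                       damaging_cutoff = 0.05) {
  nssi <- classified |> filter(category %in% NSSI_CATEGORIES)
  if (nrow(nssi) == 0) {
    return(nssi |> mutate(novel = logical(0), damaging = logical(0),
                          breeds_present = list(), specific_to = character(0)))
  }
  carriers <- variants |>
    filter(is_variant_gt(gt1, gt2)) |>
    distinct(chrom, pos, ref, alt, breed) |>
    group_by(chrom, pos, ref, alt) |>
    summarise(breeds_present = list(sort(unique(breed))), .groups = "drop")
  scores <- variants |>
    distinct(chrom, pos, ref, alt, .keep_all = TRUE) |>
    select(chrom, pos, ref, alt, dplyr::any_of(c("score", "known")))
  nssi <- nssi |>
    left_join(carriers, by = c("chrom", "pos", "ref", "alt")) |>
    left_join(scores, by = c("chrom", "pos", "ref", "alt")) |>
    mutate(breeds_present = purrr::map(breeds_present,
                                       ~ if (is.null(.x)) character(0) else .x))
  if (!is.null(known_sites)) {
    kn <- known_sites |> mutate(.known = TRUE)
    nssi <- nssi |>
      left_join(kn |> select(chrom, pos, ref, alt, .known),
                by = c("chrom", "pos", "ref", "alt")) |>
      mutate(novel = !(.data$.known %in% TRUE)) |>
      select(-".known")
  } else if ("known" %in% names(nssi)) {
    nssi <- nssi |> mutate(novel = !(known %in% TRUE))
  } else {
    nssi <- nssi |> mutate(novel = TRUE)
  }
  if ("score" %in% names(nssi)) {
    nssi <- nssi |> mutate(damaging = !is.na(score) & score < damaging_cutoff)
  } else {
    nssi <- nssi |> mutate(damaging = FALSE)
  }
  nssi |>
    select(chrom, pos, ref, alt, gene_id, category, novel, damaging,
           breeds_present) |>
    mutate(specific_to = NA_character_)
}

#' Flag breed-specific NS/SS/I variants
#'
#' A record is specific to breed X iff (1) its non-reference allele is
#' carried by X and by no other breed, (2) at the position every breed has
#' pooled read depth at least `min_depth`, and (3) in every breed the most
#' abundant allele's depth is at least `abundance_factor` times the depth of
#' each other allele (ties fail). Candidates with missing depth in any breed
#' are excluded and reported in the `skipped` attribute.
#'
#' @param nssi Output of [build_nssi()].
#' @param variants Multi-breed variants tibble with `depth` and `ad`.
#' @param min_depth Minimum pooled per-breed depth (default 10).
#' @param abundance_factor Major-allele abundance multiple (default 1.5,
#'   i.e. "50% more abundant").
#' @return `nssi` with `specific_to` set where the rule holds; records
#'   skipped for missing depth are listed in `attr(, "skipped")`.
#' @export
specific_nssi <- function(nssi, variants, min_depth = 10,
                          abundance_factor = 1.5) {
  stopifnot_cols(variants, c("breed", "chrom", "pos", "depth", "ad"),
                 "variants")
  all_breeds <- sort(unique(variants$breed))
  # pooled per-breed allele depths at each site
  depth_tab <- variants |>
    group_by(breed, chrom, pos, ref, alt) |>
    summarise(
      depth = sum(depth),
      ad = list({
        ads <- ad[!vapply(ad, is.null, logical(1))]
        if (length(ads) == 0) NULL else Reduce(`+`, ads)
      }),
      .groups = "drop"
    )
  skipped <- list()
  specific_to <- nssi$specific_to
  for (i in seq_len(nrow(nssi))) {
    carriers <- nssi$breeds_present[[i]]
    if (length(carriers) != 1L) next
    dt <- depth_tab |>
      filter(chrom == nssi$chrom[i], pos == nssi$pos[i],
             ref == nssi$ref[i], alt == nssi$alt[i])
    if (nrow(dt) < length(all_breeds) ||
        any(is.na(dt$depth)) ||
        any(vapply(dt$ad, is.null, logical(1)))) {
      skipped[[length(skipped) + 1L]] <- nssi[i, c("chrom", "pos", "ref", "alt")]
      next
    }
    ok_depth <- all(dt$depth >= min_depth)
    ok_abund <- all(vapply(dt$ad, function(a) {
      major <- max(a)
      others <- a[-which.max(a)]
      all(major >= abundance_factor * others)
    }, logical(1)))
    if (ok_depth && ok_abund) specific_to[i] <- carriers
  }
  out <- nssi
  out$specific_to <- specific_to
  attr(out, "skipped") <- bind_rows(skipped)
  out
}

#' Tag genes with economic-trait categories
#'
#' Pure join of a supplied trait map onto the gene table; genes absent from
#' the map are untagged, and a gene mapped to several categories keeps all of
#' them as a multi-category tag.
#'
#' @param genes Gene table (or any tibble with `gene_id`).
#' @param trait_map Tibble with `gene_id`, `trait`; `trait` must be one of
#'   meat, disease, growth, milk, fecundity.
#' @return `genes` with a `traits` list column (`character(0)` when untagged).
#' @export
tag_traits <- function(genes, trait_map) {
  valid <- c("meat", "disease", "growth", "milk", "fecundity")
  stopifnot_cols(trait_map, c("gene_id", "trait"), "trait map")
  bad <- !trait_map$trait %in% valid
  if (any(bad)) {
    abort(sprintf("unknown trait category '%s'; valid: %s",
                  trait_map$trait[bad][1], paste(valid, collapse = ", ")))
  }
  tags <- trait_map |>
    distinct(gene_id, trait) |>
    group_by(gene_id) |>
    summarise(traits = list(sort(trait)), .groups = "drop")
  genes |>
    left_join(tags, by = "gene_id") |>
    mutate(traits = purrr::map(traits,
                               ~ if (is.null(.x)) character(0) else .x))
}
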