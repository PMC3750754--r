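test_that("single-codon CDS substitutions match the codon-table oracle exhaustively", {
  for (strand in c("+", "-")) {
    g <- mini_genome(strand)
    gene <- g$genes[1, ]
    cds_pos <- rohscan:::gene_cds_positions(gene)
    n_checked <- 0
    for (p in sort(cds_pos)) {
      refb <- substr(g$sequences[["chrT"]], p + 1, p + 1)
      for (altb in setdiff(c("A", "C", "G", "T"), refb)) {
        got <- classify_variants(
          make_variants("chrT", p, refb, altb, 0L, 1L), g$genes, g)
        expected <- oracle_classify_snp("chrT", p, refb, altb, gene, g)
        expect_equal(got$category, expected,
                     info = sprintf("strand %s pos %d %s>%s",
                                    strand, p, refb, altb))
        n_checked <- n_checked + 1
      }
    }
    expect_equal(n_checked, 9)
  }
})

test_that("positional categories follow the gene anatomy", {
  g <- mini_genome("+")
  cases <- tibble::tribble(
    ~pos, ~expected,
    5L,  "intergenic",   # before the gene
    15L, "utr5",
    20L, NA,             # CDS, checked above
    25L, "splice_site",  # first intron base (G of GT donor)
    26L, "splice_site",
    30L, "intron",
    33L, "splice_site",  # first base of AG acceptor
    34L, "splice_site",
    24L, "utr3",         # exonic, 3' of CDS
    40L, "utr3",
    60L, "intergenic"
  ) |> dplyr::filter(!is.na(expected))
  for (i in seq_len(nrow(cases))) {
    p <- cases$pos[i]
    refb <- substr(g$sequences[["chrT"]], p + 1, p + 1)
    altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
    got <- classify_variants(make_variants("chrT", p, refb, altb, 0L, 1L),
                             g$genes, g)
    expect_equal(got$category, cases$expected[i],
                 info = sprintf("pos %d", p))
  }
})

test_that("coding indels follow the mod-3 rule and splice precedence holds", {
  g <- mini_genome("+")
  chrseq <- g$sequences[["chrT"]]
  sub_seq <- function(a, b) substr(chrseq, a + 1, b)
  # 2 bp deletion inside CDS (deletes pos 21,22): frameshift
  del2 <- make_variants("chrT", 20L, sub_seq(20, 23), sub_seq(20, 21), 0L, 1L)
  expect_equal(classify_variants(del2, g$genes, g)$category, "frameshift_indel")
  # 3 bp deletion covering the codon (anchor at 19): in-frame
  del3 <- make_variants("chrT", 19L, sub_seq(19, 23), sub_seq(19, 20), 0L, 1L)
  expect_equal(classify_variants(del3, g$genes, g)$category, "inframe_indel")
  # 3 bp insertion inside the CDS: in-frame; 1 bp insertion: frameshift
  ins3 <- make_variants("chrT", 20L, sub_seq(20, 21),
                        paste0(sub_seq(20, 21), "AAA"), 0L, 1L)
  expect_equal(classify_variants(ins3, g$genes, g)$category, "inframe_indel")
  ins1 <- make_variants("chrT", 20L, sub_seq(20, 21),
                        paste0(sub_seq(20, 21), "A"), 0L, 1L)
  expect_equal(classify_variants(ins1, g$genes, g)$category, "frameshift_indel")
  # deletion hitting the donor dinucleotide but not the CDS: splice_site
  del_splice <- make_variants("chrT", 24L, sub_seq(24, 27), sub_seq(24, 25),
                              0L, 1L)
  expect_equal(classify_variants(del_splice, g$genes, g)$category,
               "splice_site")
})

test_that("classification is strand-symmetric under genome mirroring", {
  ref <- generate_reference(1, 60000, 3, seed = 41)
  mir <- mirror_genome(ref)
  set.seed(42)
  spans <- rohscan:::gene_spans(ref$genes)
  pos <- unlist(lapply(seq_len(nrow(spans)), function(i) {
    sample(seq(spans$start[i] - 30, spans$end[i] + 30), 60)
  }))
  refb <- vapply(pos, function(p) substr(ref$sequences[["chr1"]], p + 1, p + 1),
                 character(1))
  altb <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                 character(1))
  v <- make_variants("chr1", pos, "A", "C", 0L, 1L)
  v$ref <- refb; v$alt <- altb
  cls <- classify_variants(v, ref$genes, ref) |>
    dplyr::arrange(pos, gene_id)
  L <- ref$lengths[["chr1"]]
  vm <- mirror_snps(v, ref$lengths)
  clsm <- classify_variants(vm, mir$genes, mir) |>
    dplyr::mutate(pos = L - 1L - pos) |>
    dplyr::arrange(pos, gene_id)
  expect_equal(cls$category, clsm$category)
  expect_equal(cls$pos, clsm$pos)
})

test_that("category partition: one category per (variant, gene), all sites covered", {
  ref <- generate_reference(1, 200000, 5, seed = 23)
  plan <- sim_plan(breeds = c(HW = 1L), snp_rate = 1 / 200, seed = 23)
  cs <- simulate_callsets(ref, plan)
  cls <- classify_variants(cs$variants, ref$genes, ref)
  expect_equal(anyDuplicated(cls[, c("chrom", "pos", "ref", "alt", "gene_id")]),
               0)
  expect_true(all(cls$category %in% rohscan:::CONSEQUENCE_LEVELS))
  n_sites <- nrow(dplyr::distinct(cs$variants, chrom, pos, ref, alt))
  covered <- dplyr::n_distinct(paste(cls$chrom, cls$pos, cls$ref, cls$alt))
  expect_equal(covered, n_sites)
})

test_that("NS/SS/I selection keeps only protein-affecting categories with flags", {
  # synonymous-only input yields an empty set
  g <- mini_genome("+")
  syn <- make_variants("chrT", 22L, "A", "G", 0L, 1L)  # GGA>GGG
  cls_syn <- classify_variants(syn, g$genes, g)
  expect_equal(cls_syn$category, "synonymous")
  expect_equal(nrow(build_nssi(cls_syn, syn)), 0)

  # missense with score and known flags: strict < 0.05 damaging rule
  mis <- make_variants("chrT", 21L, "G", "A", 0L, 1L,
                       score = c(0.049), known = FALSE)
  cls <- classify_variants(mis, g$genes, g)
  expect_equal(cls$category, "missense")
  n1 <- build_nssi(cls, mis)
  expect_true(n1$damaging)
  expect_true(n1$novel)
  mis2 <- mis; mis2$score <- 0.05
  expect_false(build_nssi(cls, mis2)$damaging)
  mis3 <- mis; mis3$known <- TRUE
  expect_false(build_nssi(cls, mis3)$novel)
  # known catalogue argument overrides the column
  ks <- tibble::tibble(chrom = "chrT", pos = 21L, ref = "G", alt = "A")
  expect_false(build_nssi(cls, mis, known_sites = ks)$novel)

  # breeds_present collects carriers of non-reference genotypes only
  multi <- dplyr::bind_rows(
    make_variants("chrT", 21L, "G", "A", 0L, 1L, breed = "HW",
                  sample_id = "HW_01"),
    make_variants("chrT", 21L, "G", "A", 0L, 0L, breed = "BA",
                  sample_id = "BA_01")
  )
  nb <- build_nssi(cls, multi)
  expect_equal(nb$breeds_present[[1]], "HW")
})

test_that("breed-specific NS/SS/I rule enforces depth, abundance and exclusivity", {
  g <- mini_genome("+")
  mk <- function(ads, gts, depth_override = NULL) {
    breeds <- c("HW", "BA", "HO")
    dplyr::bind_rows(lapply(seq_along(breeds), function(i) {
      v <- make_variants("chrT", 21L, "G", "A", gts[[i]][1], gts[[i]][2],
                         breed = breeds[i],
                         sample_id = paste0(breeds[i], "_01"))
      v$ad <- list(ads[[i]])
      v$depth <- if (is.null(depth_override)) sum(ads[[i]]) else
        depth_override[i]
      v
    }))
  }
  cls <- classify_variants(make_variants("chrT", 21L, "G", "A", 0L, 1L),
                           g$genes, g)
  # carrier (4,12): 12 >= 1.5*4; others (15,0): 15 >= 1.5*0 -> specific
  v <- mk(list(c(4L, 12L), c(15L, 0L), c(15L, 0L)),
          list(c(0L, 1L), c(0L, 0L), c(0L, 0L)))
  out <- specific_nssi(build_nssi(cls, v), v)
  expect_equal(out$specific_to, "HW")
  # depth 9 in any breed kills it
  v9 <- mk(list(c(4L, 12L), c(9L, 0L), c(15L, 0L)),
           list(c(0L, 1L), c(0L, 0L), c(0L, 0L)))
  expect_true(is.na(specific_nssi(build_nssi(cls, v9), v9)$specific_to))
  # tie depths fail the abundance rule
  vt <- mk(list(c(8L, 8L), c(15L, 0L), c(15L, 0L)),
           list(c(0L, 1L), c(0L, 0L), c(0L, 0L)))
  expect_true(is.na(specific_nssi(build_nssi(cls, vt), vt)$specific_to))
  # alt carried by two breeds: not specific regardless of depths
  v2 <- mk(list(c(4L, 12L), c(4L, 12L), c(15L, 0L)),
           list(c(0L, 1L), c(0L, 1L), c(0L, 0L)))
  expect_true(is.na(specific_nssi(build_nssi(cls, v2), v2)$specific_to))
  # missing depth in one breed: excluded and logged
  vm <- mk(list(c(4L, 12L), c(15L, 0L), c(15L, 0L)),
           list(c(0L, 1L), c(0L, 0L), c(0L, 0L)))
  vm$ad[vm$breed == "HO"] <- list(NULL)
  res <- specific_nssi(build_nssi(cls, vm), vm)
  expect_true(is.na(res$specific_to))
  expect_equal(nrow(attr(res, "skipped")), 1)
})

test_that("trait tagging is a pure join with multi-category tags", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"))
  empty <- tag_traits(genes, tibble::tibble(gene_id = character(0),
                                            trait = character(0)))
  expect_true(all(lengths(empty$traits) == 0))
  one <- tag_traits(genes, tibble::tibble(gene_id = "g1", trait = "meat"))
  expect_equal(one$traits[[1]], "meat")
  expect_length(one$traits[[2]], 0)
  multi <- tag_traits(genes, tibble::tibble(gene_id = c("g1", "g1"),
                                            trait = c("meat", "disease")))
  expect_setequal(multi$traits[[1]], c("meat", "disease"))
  expect_error(tag_traits(genes, tibble::tibble(gene_id = "g1",
                                                trait = "wool")),
               "unknown trait")
})
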