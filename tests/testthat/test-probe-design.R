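test_that("flank screen classifies by polymorphism distance and count", {
  mkTab <- function(extra_pos, files = "f01")
    toyPanel(rbind(snpObs("f01", pos = 500L),
                   do.call(rbind, lapply(extra_pos, function(p)
                     snpObs(files, pos = p, alt = "G")))), files = F8)
  # one polymorphism 15 bases away
  expect_equal(screenFlanks(mkTab(515L), "chr1", 500L, "reverse"),
               "not_recommended")
  # one polymorphism 22 bases away, none closer
  expect_equal(screenFlanks(mkTab(522L), "chr1", 500L, "reverse"), "neutral")
  # none within 24 bases
  expect_equal(screenFlanks(mkTab(530L), "chr1", 500L, "reverse"),
               "recommended")
  # three polymorphisms at 21-24 bases: more than 2 within 24
  expect_equal(screenFlanks(mkTab(c(521L, 522L, 523L)), "chr1", 500L,
                            "reverse"), "not_recommended")
  # the forward screen looks upstream
  expect_equal(screenFlanks(mkTab(515L), "chr1", 500L, "forward"),
               "recommended")
})

test_that("16-mer counting equals a brute-force substring scan", {
  set.seed(5)
  bases <- c("A", "C", "G", "T")
  refseq <- paste(sample(bases, 4000, TRUE), collapse = "")
  ref <- Biostrings::DNAStringSet(setNames(refseq, "chr1"))
  bruteCount <- function(probe, refseq) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(refseq)))
    total <- 0L
    for (i in seq_len(nchar(probe) - 15L)) {
      km <- substr(probe, i, i + 15L)
      for (s in c(refseq, rc)) {
        j <- 1L
        while ((hit <- regexpr(km, substr(s, j, nchar(s)), fixed = TRUE)) > 0) {
          total <- total + 1L
          j <- j + hit
        }
      }
    }
    total
  }
  # a 30-mer embedded once: one hit per 16-mer
  probe <- substr(refseq, 1001, 1030)
  res <- kmerUniqueness(probe, ref)
  expect_equal(res$matches, bruteCount(probe, refseq))
  expect_equal(res$matches, 15L)
  expect_true(res$pass)
  # a probe absent from the reference
  res0 <- kmerUniqueness(paste(rep("AC", 10), collapse = ""), ref)
  expect_equal(res0$matches, bruteCount(paste(rep("AC", 10), collapse = ""),
                                        refseq))
  # a 16-mer repeated 301 times fails
  unit <- "ACGTACGTACGTACGT"
  rep_ref <- Biostrings::DNAStringSet(setNames(
    paste(rep(unit, 80), collapse = ""), "chr1"))
  res301 <- kmerUniqueness(unit, rep_ref)
  expect_gt(res301$matches, 300L)
  expect_false(res301$pass)
  expect_error(kmerUniqueness("ACGT", ref), "16 bases")
})

test_that("score classification follows the 0.4 / 0.7 thresholds", {
  expect_equal(classifyScore(c(0.39, 0.4, 0.55, 0.7, 0.71, NA)),
               c("not_recommended", "neutral", "neutral", "neutral",
                 "recommended", "unscored"))
})

test_that("eligibility admits by category with priority ordering", {
  expect_false(eligibility("diallelic_snp", "neutral")$admit)
  expect_true(eligibility("haplosnp_snpsnp", "neutral")$admit)
  expect_true(eligibility("msnp", "recommended")$admit)
  expect_false(eligibility("msnp", "not_recommended")$admit)
  expect_false(eligibility("diallelic_snp", "recommended",
                           kmer_pass = FALSE)$admit)
  # unscored counts as neutral: blocks standard, passes ploidy-reducing
  expect_false(eligibility("codon_based", "recommended",
                           score_class = "unscored")$admit)
  expect_true(eligibility("snp_in_insertion", "recommended",
                          score_class = "unscored")$admit)
  expect_equal(eligibility("msnp", "neutral")$priority, 1L)
  expect_equal(eligibility("diallelic_snp", "recommended",
                           score_class = "recommended")$priority, 2L)
  expect_equal(eligibility("codon_based", "recommended")$priority, 4L)
})

test_that("tiling produces the per-category probe counts and sequences", {
  set.seed(2)
  refseq <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  ref <- Biostrings::DNAStringSet(setNames(refseq, "chr1"))
  row <- function(category, pos, alleles, atgc = FALSE, strand = "both",
                  destab_pos = NA, destab_type = NA, destab_ref = NA,
                  destab_alt = NA)
    data.frame(category = category, chrom = "chr1", pos = pos, ref = "A",
               alleles = alleles, n_alleles = 2L, atgc = atgc,
               strand = strand, destab_pos = destab_pos,
               destab_type = destab_type, destab_ref = destab_ref,
               destab_alt = destab_alt, offset = NA, safety = "BothSafe",
               flank_up = NA, flank_down = NA, provenance = "",
               stringsAsFactors = FALSE)
  # di-allelic A/G on both strands: 2 probes, sequences match the reference
  tp <- buildTiling(row("diallelic_snp", 200L, "A/G"), reference = ref)
  expect_equal(nrow(tp), 2L)
  expect_equal(tp$sequence[tp$strand == "forward"], substr(refseq, 170, 199))
  expect_equal(tp$sequence[tp$strand == "reverse"],
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(refseq, 201, 230)))))
  # mSNP on both strands: 8 distinct probes, 4 per strand
  tm <- buildTiling(row("msnp", 200L, "A/C/G"), reference = ref)
  expect_equal(nrow(tm), 8L)
  expect_equal(length(unique(tm$sequence)), 8L)
  expect_equal(sum(tm$strand == "forward"), 4L)
  # indel with A/T context on a single strand: 2 allele-specific probes
  ti <- buildTiling(row("indel", 200L, "A/T", atgc = TRUE),
                    strands = "forward", reference = ref)
  expect_equal(nrow(ti), 2L)
  expect_true(all(ti$allele_specific))
  # SNP-SNP sites are single-strand: the other strand errors
  hp <- row("haplosnp_snpsnp", 200L, "A/C", strand = "reverse",
            destab_pos = 204L, destab_type = "snp", destab_ref = "G",
            destab_alt = "T")
  expect_error(buildTiling(hp, strands = "forward", reference = ref),
               "reverse strand")
  tphp <- buildTiling(hp, strands = "reverse", reference = ref)
  expect_equal(nrow(tphp), 1L)
  # the probe template carries the critical (destabilising) base
  win <- substr(refseq, 201, 230)
  substr(win, 4, 4) <- "T"
  expect_equal(tphp$sequence,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(win))))
  # determinism
  expect_identical(tp, buildTiling(row("diallelic_snp", 200L, "A/G"),
                                   reference = ref))
})

test_that("accounting reproduces per-category identities on arbitrary plans", {
  plan <- rbind(tilingPlan("diallelic_snp", n_single = 5, n_both = 3),
                tilingPlan("msnp", n_single = 2, n_both = 1),
                tilingPlan("indel", n_single = 4, n_atgc_single = 2,
                           n_both = 1))
  s <- accountDesign(plan)
  get <- function(cat, col) s[s$category == cat, col]
  expect_equal(get("diallelic_snp", "n_probes"), 5 + 6)
  expect_equal(get("diallelic_snp", "n_probesets"), 11)
  expect_equal(get("msnp", "n_probes"), (2 + 2) * 4)
  expect_equal(get("msnp", "n_probesets"), (2 + 2) * 6)
  expect_equal(get("indel", "n_probes"), 4 + 2 * 2 + 2)
  expect_equal(get("indel", "n_probesets"), 4 + 2 + 2)
  # probes >= probesets for every category except mSNP (whose 6 pairwise
  # probesets per strand exceed its 4 probes); features double the probes
  non_msnp <- s$category != "msnp" & s$category != "total"
  expect_true(all(s$n_probes[non_msnp] >= s$n_probesets[non_msnp]))
  expect_equal(s$n_features, 2L * s$n_probes)
  # a both-strand site contributes exactly twice its single-strand probesets
  one_single <- accountDesign(tilingPlan("diallelic_snp", n_single = 1))
  one_both <- accountDesign(tilingPlan("diallelic_snp", n_both = 1))
  expect_equal(one_both$n_probesets[1], 2L * one_single$n_probesets[1])
  # removing a site decreases every counter consistently
  s2 <- accountDesign(plan[-1, ])
  tot <- s[s$category == "total", -1]; tot2 <- s2[s2$category == "total", -1]
  expect_equal(tot$n_target_sites - tot2$n_target_sites, 1)
  expect_equal(tot$n_probes - tot2$n_probes, 1)
  # per-category A/T-G/C probeset convention is switchable
  ps <- accountDesign(tilingPlan("haplosnp_indelsnp", n_atgc_single = 1))
  expect_equal(ps$n_probesets[1], 2L)   # pair counts as two probesets
  ps1 <- accountDesign(tilingPlan("haplosnp_indelsnp", n_atgc_single = 1),
                       pair_one_probeset = c(haplosnp_indelsnp = TRUE))
  expect_equal(ps1$n_probesets[1], 1L)
})
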