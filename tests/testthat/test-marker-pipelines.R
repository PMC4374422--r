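test_that("read-count filter applies per-type thresholds summed over files", {
  obs <- rbind(snpObs("f01", pos = 100L, AO = 1L),
               snpObs("f02", pos = 100L, AO = 1L),          # snp, 2 reads
               snpObs("f01", pos = 300L, AO = 2L),
               snpObs("f02", pos = 300L, AO = 1L),          # snp, 3 reads
               data.frame(file = c("f01", "f02"), chrom = "chr1", pos = 500L,
                          ref = "ATTT", alt = "A", AO = 1L)) # indel, 2 reads
  tab <- toyPanel(obs, files = F8)
  v <- variantRecords(tab)
  keep <- readCountFilter(tab)
  expect_false(keep[v$pos == 100])   # < 3 for SNPs: drop
  expect_true(keep[v$pos == 300])    # boundary: keep
  expect_true(keep[v$pos == 500])    # 2 reads suffice for indels
})

test_that("presence/absence filter keeps segregating variants and names reasons", {
  obs <- rbind(snpObs(c("f01", "f02"), pos = 100L),        # present 2 of 8
               snpObs(F8, pos = 300L),                     # present in all
               snpObs("f01", pos = 500L, alt = "G"))       # present 1
  tab <- toyPanel(obs, files = F8)
  v <- variantRecords(tab)
  res <- presenceAbsenceFilter(tab)
  expect_true(res$keep[v$pos == 100])
  expect_false(res$keep[v$pos == 300])
  expect_equal(res$reason[v$pos == 300], "HSV-like")
  expect_false(res$keep[v$pos == 500])
  expect_equal(res$reason[v$pos == 500], "insufficient presence")
  # subpanel too small for the thresholds
  tiny <- toyPanel(snpObs(c("f01", "f02"), pos = 100L), files = c("f01", "f02", "f03"))
  expect_error(presenceAbsenceFilter(tiny), "cannot require")
})

test_that("A/T-G/C filter drops exactly the two transversion pairs", {
  expect_false(atGcFilter("A", "T"))
  expect_false(atGcFilter("T", "A"))
  expect_false(atGcFilter("C", "G"))
  expect_true(atGcFilter("A", "G"))
  expect_true(atGcFilter("C", "T"))
  expect_true(atGcFilter("G", "T"))
  expect_error(atGcFilter("AT", "A"), "single-base")
})

test_that("genic filter distinguishes CDS, intron and intergenic sites", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(100, 100, 300), c(400, 199, 400)))
  gr$type <- c("gene", "CDS", "CDS"); gr$gene <- "g1"
  cfg_cds <- pipelineConfig(genic_mode = "CDS")
  cfg_gen <- pipelineConfig(genic_mode = "genic")
  expect_false(genicFilter("chr1", 500L, gr, cfg_cds))   # intergenic
  expect_false(genicFilter("chr1", 250L, gr, cfg_cds))   # intron, CDS mode
  expect_true(genicFilter("chr1", 250L, gr, cfg_gen))    # intron, genic mode
  expect_true(genicFilter("chr1", 150L, gr, cfg_cds))    # CDS
  expect_true(genicFilter("chr1", 500L, gr, pipelineConfig()))  # mode none
  cfg_un <- pipelineConfig(exclude_unanchored = TRUE,
                           unanchored_chroms = "chr0")
  expect_false(genicFilter("chr0", 500L, NULL, cfg_un))
})

test_that("flank safety honours window boundaries and the haploSNP exception", {
  obs <- rbind(snpObs("f01", pos = 100L),
               snpObs("f01", pos = 75L, alt = "G"),   # 25 bp upstream
               snpObs("f01", pos = 125L, alt = "G"))  # 25 bp downstream
  tab <- toyPanel(obs, files = F8)
  expect_equal(flankSafety(tab, "chr1", 100L), "BothSafe")
  # variant 10 bp downstream
  tab2 <- toyPanel(rbind(obs, snpObs("f01", pos = 110L, alt = "G")),
                   files = F8)
  expect_equal(flankSafety(tab2, "chr1", 100L), "UpSafe-only")
  # only the destabilising HSV at offset 4 in the window: safe
  tab3 <- toyPanel(rbind(snpObs("f01", pos = 100L),
                         snpObs(F8, pos = 104L, alt = "G")), files = F8)
  expect_equal(flankSafety(tab3, "chr1", 100L, exception_pos = 104L),
               "BothSafe")
  expect_equal(flankSafety(tab3, "chr1", 100L), "UpSafe-only")
})

test_that("di-allelic pipeline excludes tri-allelic, A/T and HSV-like sites", {
  obs <- rbind(snpObs(c("f01", "f02"), pos = 100L, ref = "A", alt = "C"),
               snpObs(c("f01", "f02"), pos = 200L, ref = "A", alt = "T"),
               snpObs(c("f01", "f02"), pos = 300L, ref = "A", alt = "C"),
               snpObs(c("f03", "f04"), pos = 300L, ref = "A", alt = "G"),
               snpObs(F8, pos = 400L, ref = "A", alt = "C"))
  tab <- toyPanel(obs, files = F8)
  cand <- discoverDiallelicSnps(tab)
  expect_equal(cand$pos, 100L)
  msnp <- discoverMsnps(tab)
  expect_equal(msnp$pos, 300L)      # tri-allelic site routed to mSNP
  expect_equal(msnp$n_alleles, 3L)
})

test_that("indel pipeline enforces size range and the 24/30 windows", {
  del4 <- function(file, pos, AO = 5L)
    data.frame(file = file, chrom = "chr1", pos = pos,
               ref = "ACGTA", alt = "A", AO = AO, stringsAsFactors = FALSE)
  del8 <- function(file, pos)
    data.frame(file = file, chrom = "chr1", pos = pos,
               ref = "ACGTACGTA", alt = "A", AO = 5L, stringsAsFactors = FALSE)
  obs <- rbind(del4(c("f01", "f02"), 100L),
               del8(c("f01", "f02"), 300L),
               del4(c("f01", "f02"), 500L),
               snpObs("f03", pos = 528L, alt = "G"))  # 28 bp downstream
  tab <- toyPanel(obs, files = F8)
  cand <- discoverIndels(tab)
  expect_equal(cand$pos, 100L)   # 8 bp indel and window-violating site excluded
})

test_that("haploSNP pairing obeys distance rules, clean window and coupling", {
  mk <- snpObs(c("f01", "f02"), pos = 100L)
  hsv4 <- snpObs(F8, pos = 104L, alt = "G")
  hsv7 <- snpObs(F8, pos = 207L, alt = "G")
  mk2 <- snpObs(c("f01", "f02"), pos = 200L)
  tab <- toyPanel(rbind(mk, hsv4, mk2, hsv7), files = F8)
  cand <- discoverHaploSnps(tab, strategy = "snp_snp")
  expect_equal(cand$pos, 100L)          # offset 7 pair rejected
  expect_equal(cand$offset, 4L)
  expect_equal(cand$destab_pos, 104L)
  expect_equal(cand$strand, "reverse")  # destabiliser downstream
  # a third variant inside the clean window kills the pair
  tab2 <- toyPanel(rbind(mk, hsv4, snpObs("f05", pos = 112L, alt = "G")),
                   files = F8)
  expect_equal(nrow(discoverHaploSnps(tab2, strategy = "snp_snp")), 0L)
  # coupling: marker carrier lacking the critical form is rejected
  hsv_partial <- snpObs(setdiff(F8, "f01"), pos = 104L, alt = "G")
  tab3 <- toyPanel(rbind(mk, hsv_partial), files = F8)
  expect_equal(nrow(discoverHaploSnps(tab3, strategy = "snp_snp")), 0L)
})

test_that("indel-SNP strategy requires a 4-6 bp fixed indel within 14 bp", {
  mk <- snpObs(c("f01", "f02"), pos = 100L)
  ins5 <- data.frame(file = F8, chrom = "chr1", pos = 110L, ref = "A",
                     alt = "ACGTAC", AO = 5L)
  tab <- toyPanel(rbind(mk, ins5), files = F8)
  cand <- discoverHaploSnps(tab, strategy = "indel_snp")
  expect_equal(cand$pos, 100L)
  expect_equal(cand$offset, 10L)
  # 3 bp destabiliser is out of the 4-6 bp range
  ins3 <- data.frame(file = F8, chrom = "chr1", pos = 110L, ref = "A",
                     alt = "ACGT", AO = 5L)
  tab2 <- toyPanel(rbind(mk, ins3), files = F8)
  expect_equal(nrow(discoverHaploSnps(tab2, strategy = "indel_snp")), 0L)
})

test_that("SNP-in-insertion requires a fixed insertion with one variable base", {
  carr <- c("f01", "f02")
  rest <- setdiff(F8, carr)
  obs <- rbind(
    data.frame(file = carr, chrom = "chr1", pos = 100L, ref = "A",
               alt = "ACGTA", AO = 5L),
    data.frame(file = rest, chrom = "chr1", pos = 100L, ref = "A",
               alt = "ACTTA", AO = 5L))
  tab <- toyPanel(obs, files = F8)
  cand <- discoverHaploSnps(tab, strategy = "snp_in_insertion")
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$offset, 2L)      # variable base: 2nd inserted base
  expect_equal(cand$category, "snp_in_insertion")
  # not fixed across the panel: no candidate
  tab2 <- toyPanel(obs[obs$file != "f08", ], files = F8)
  expect_equal(nrow(discoverHaploSnps(tab2, strategy = "snp_in_insertion")), 0L)
})

test_that("diploid pipeline needs heterozygosity and jointly clean flanks", {
  dip <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                    ref = "A", alt = "C", type = "snp",
                    DP = c(30L, 30L, 30L), RO = c(15L, 0L, 15L),
                    AO = c(15L, 30L, 15L), stringsAsFactors = FALSE)
  tab <- toyPanel(snpObs("f01", pos = 305L, alt = "G"), files = F8)
  cand <- discoverDiploidParentSnps(dip, tab)
  expect_equal(cand$pos, 100L)  # hom-alt site and panel-adjacent site excluded
})

test_that("codon mining finds strand-corrected proline third positions", {
  # + strand gene: CCA at CDS start; - strand gene encodes CCT on its strand
  seqs <- paste0("AAAA", "CCATTTGGG", "TTTT", "TTTAGGTTT", "AAAA")
  #               1-4    5-13 (+)     14-17  18-26 (-)     27-30
  ref <- Biostrings::DNAStringSet(setNames(seqs, "chr1"))
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(5, 5, 18, 18), c(13, 13, 26, 26)),
                               strand = c("+", "+", "-", "-"))
  gr$type <- c("gene", "CDS", "gene", "CDS"); gr$gene <- c("g1", "g1", "g2", "g2")
  tab <- toyPanel(snpObs("f01", pos = 1000L), files = F8)  # empty-ish panel
  cand <- findCodonSites(ref, gr, tab)
  # g1 (+): codons CCA TTT GGG -> proline codon 1, third base at pos 7
  expect_true(7L %in% cand$pos)
  # g2 (-): transcript is revcomp(TTTAGGTTT) = AAACCTAAA -> codon 2 = CCT,
  # third base of that codon maps to genome position 21
  expect_true(21L %in% cand$pos)
  expect_equal(sort(cand$pos), c(7L, 21L))
  expect_equal(cand$strand[cand$pos == 21L], "reverse")
})

test_that("spread selection matches a brute-force max-min oracle", {
  bruteMaxMin <- function(pos, k) {
    combs <- utils::combn(sort(pos), k)
    max(apply(combs, 2, function(s) min(diff(s))))
  }
  set.seed(11)
  for (trial in 1:10) {
    pos <- sort(sample.int(1000, sample(5:9, 1)))
    k <- sample(2:4, 1)
    cand <- data.frame(category = "diallelic_snp", chrom = "chr1", pos = pos)
    sel <- spreadSelection(cand, n_target = k)
    expect_equal(nrow(sel), k)
    expect_equal(min(diff(sort(sel$pos))), bruteMaxMin(pos, k))
  }
})

test_that("spread selection keeps the far candidate and dedupes by precedence", {
  pos <- c(100:109, 5000)
  cand <- data.frame(category = "diallelic_snp", chrom = "chr1", pos = pos)
  sel <- spreadSelection(cand, n_target = 2)
  expect_true(5000 %in% sel$pos)
  expect_equal(nrow(sel), 2L)
  # n_target >= n retains everything
  expect_equal(nrow(spreadSelection(cand, n_target = 50)), length(pos))
  # duplicate coordinate across categories: higher-precedence category wins
  dup <- data.frame(category = c("codon_based", "msnp"), chrom = "chr1",
                    pos = c(100L, 100L))
  sel <- spreadSelection(dup, n_target = 10)
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$category, "msnp")
})

test_that("emitted candidates re-pass their category filters (idempotence)", {
  p <- smallPanelCached()
  tab <- makePanelTable(p)
  cfg <- pipelineConfig()
  cand <- discoverDiallelicSnps(tab)
  v <- variantRecords(tab)
  for (i in seq_len(nrow(cand))) {
    j <- which(v$chrom == cand$chrom[i] & v$pos == cand$pos[i])
    expect_length(j, 1L)
    expect_true(readCountFilter(tab, j, cfg))
    expect_true(presenceAbsenceFilter(tab, j, cfg)$keep)
    expect_true(atGcFilter(v$ref[j], v$alt[j]))
    expect_equal(flankSafety(tab, v$chrom[j], v$pos[j]), "BothSafe")
  }
  hap <- discoverHaploSnps(tab, cfg, "snp_snp")
  for (i in seq_len(nrow(hap))) {
    expect_lte(hap$offset[i], cfg$snpsnp_max_offset)
    expect_gte(hap$offset[i], 1L)
    expect_equal(flankSafety(tab, hap$chrom[i], hap$pos[i],
                             exception_pos = hap$destab_pos[i]), "BothSafe")
  }
})

test_that("raising min_present never increases candidate counts", {
  p <- smallPanelCached()
  tab <- makePanelTable(p)
  counts <- vapply(2:5, function(mp)
    nrow(discoverDiallelicSnps(tab, pipelineConfig(min_present = mp))), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("categories are coordinate-disjoint after spread selection", {
  p <- smallPanelCached()
  tab <- makePanelTable(p)
  res <- discoverAll(tab, reference = p@reference, gene_models = p@genes,
                     diploid_records = p@diploid_vcf)
  sel <- spreadSelection(res$combined, n_target = 100)
  expect_false(any(duplicated(paste(sel$chrom, sel$pos))))
})
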