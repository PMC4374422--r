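BASES <- c("A", "C", "G", "T")

# unordered allele pairs excluded by the A/T-G/C filter
.isAtGcPair <- function(a, b) {
  p <- paste(pmin(a, b), pmax(a, b))
  p == "A T" | p == "C G"
}

# alt base for `ref` that keeps the pair off the A/T-G/C exclusion list
.safeAlt <- function(ref, rng_choice) {
  ok <- BASES[BASES != ref & !.isAtGcPair(BASES, ref)]
  ok[1 + (rng_choice %% length(ok))]
}

.randSeq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Generate a synthetic allo-octoploid discovery panel
#'
#' Builds a random diploid reference split into chromosomes, collapses
#' `n_subgenomes` homoeologs onto it, and plants, at flank-safe spacing:
#' fixed homoeologous sequence variants (HSV SNPs and indels, carried by
#' every accession), segregating di-allelic marker SNPs and 3-6 bp marker
#' indels, multi-allelic sites (a segregating allele plus a fixed
#' background allele), the three haploSNP configurations (marker SNP
#' coupled to a destabilising HSV within the strategy's distance bound),
#' heterozygous sites private to a diploid outgroup sample, and a set of
#' deliberate filter-violating decoys. Deletion blocks remove whole
#' subgenome segments, reducing local read depth and effective ploidy.
#' Per-file supporting read counts are Poisson draws proportional to the
#' number of non-deleted homoeologous copies carrying the allele times the
#' file's coverage, truncated below at `min_alt_reads` for carriers
#' (a record is only emitted where the caller would have emitted one).
#'
#' All randomness derives from `config@seed`: identical configs give
#' byte-identical outputs.
#'
#' @param config a [SimConfig-class].
#' @return A [SyntheticPanel-class]. The `truth` slot has one row per
#'   planted variant with columns chrom, pos, kind, subgenome, ref, alt,
#'   carriers (semicolon-joined accession ids; all accessions for HSVs),
#'   destab_pos/destab_type/destab_alt/offset for haploSNPs,
#'   effective_ploidy, in_deletion, satisfies (TRUE when the record was
#'   planted to satisfy every filter of its category) and note.
#' @seealso [writePanel()], [makePanelTable()], [generatePedigree()],
#'   [generateIntensities()]
#' @export
generatePanel <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  n_sub <- config@n_subgenomes
  n_acc <- config@n_accessions
  acc_ids <- sprintf("acc%02d", seq_len(n_acc))
  file_acc <- acc_ids
  if (config@duplicate_first_accession)
    file_acc <- c(acc_ids[1], acc_ids[1], acc_ids[-1])
  file_ids <- sprintf("%s_f%02d", file_acc, seq_along(file_acc))
  names(file_acc) <- file_ids
  cov <- setNames(config@mean_depth, file_ids)

  ## reference -----------------------------------------------------------
  chr_len <- rep(config@ref_length %/% config@n_chromosomes, config@n_chromosomes)
  chr_len[1] <- chr_len[1] + config@ref_length %% config@n_chromosomes
  chroms <- sprintf("chr%d", seq_len(config@n_chromosomes))
  ref <- Biostrings::DNAStringSet(vapply(chr_len, .randSeq, ""))
  names(ref) <- chroms

  ## deletion blocks (fixed in the panel; whole-subgenome segments) ------
  deletions <- data.frame(chrom = character(), start = integer(),
                          end = integer(), subgenomes = character(),
                          stringsAsFactors = FALSE)
  if (config@deletion_block_count > 0) {
    # non-overlapping blocks: one per equal-width segment of its chromosome
    chrom_of <- 1 + (seq_len(config@deletion_block_count) - 1) %% length(chroms)
    for (ci in unique(chrom_of)) {
      m <- sum(chrom_of == ci)
      L <- chr_len[ci]
      seg <- L %/% m
      bl <- min(config@deletion_block_length, seg %/% 2)
      for (j in seq_len(m)) {
        lo <- (j - 1L) * seg + 1L
        start <- lo + sample.int(seg - bl, 1)
        k <- sample(1:(n_sub - 1), 1)
        subs <- sort(sample(seq_len(n_sub), k))
        deletions <- rbind(deletions, data.frame(
          chrom = chroms[ci], start = start, end = start + bl - 1L,
          subgenomes = paste(subs, collapse = ","), stringsAsFactors = FALSE))
      }
    }
  }
  deletedSubs <- function(chrom, pos) {
    hit <- deletions$chrom == chrom & deletions$start <= pos & deletions$end >= pos
    if (!any(hit)) integer() else
      unique(unlist(lapply(strsplit(deletions$subgenomes[hit], ","), as.integer)))
  }

  ## slot allocation: planted variants sit >= `slot_w` apart so that every
  ## planted marker is flank-clean by construction (24/30 bp windows)
  slot_w <- 160L
  margin <- 100L
  slots <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    p <- seq.int(margin, chr_len[i] - margin, by = slot_w)
    data.frame(chrom = chroms[i], pos = p, stringsAsFactors = FALSE)
  }))
  slots <- slots[sample.int(nrow(slots)), ]

  kb <- config@ref_length / 1000
  n_haplo <- round(config@haplosnp_rate * kb)
  counts <- c(
    hsv_snp = round(config@hsv_rate * kb * 0.8),
    hsv_indel = round(config@hsv_rate * kb * 0.2),
    diallelic_snp = round(config@marker_rate * kb),
    indel = round(config@indel_marker_rate * kb),
    msnp = round(config@msnp_rate * kb),
    haplosnp_snpsnp = n_haplo %/% 3 + n_haplo %% 3,
    haplosnp_indelsnp = n_haplo %/% 3,
    snp_in_insertion = n_haplo %/% 3,
    diploid_snp = round(config@diploid_marker_rate * kb),
    decoy = round(config@decoy_rate * kb))
  if (sum(counts) > nrow(slots))
    stop("window collision: ", sum(counts), " planted variants exceed the ",
         nrow(slots), " flank-safe slots available (first rejected kind: ",
         names(counts)[which.max(cumsum(counts) > nrow(slots))],
         "); reduce rates or enlarge ref_length")

  take <- function(n) {
    out <- slots[seq_len(n), , drop = FALSE]
    slots <<- slots[-seq_len(n), , drop = FALSE]
    out
  }
  refBase <- function(chrom, pos)
    as.character(Biostrings::subseq(ref[[chrom]], pos, pos))
  refSeq <- function(chrom, from, to)
    as.character(Biostrings::subseq(ref[[chrom]], from, to))

  pickSub <- function(chrom, pos) {
    avail <- setdiff(seq_len(n_sub), deletedSubs(chrom, pos))
    if (!length(avail)) NA_integer_ else
      avail[sample.int(length(avail), 1)]
  }
  pickCarriers <- function() {
    k <- sample(2:(n_acc - 2), 1)
    sort(sample(acc_ids, k))
  }

  truth <- list()
  obs <- list()   # rows: file, chrom, pos, ref, alt, type, copies
  addObs <- function(files, chrom, pos, refA, altA, type, copies) {
    obs[[length(obs) + 1L]] <<- data.frame(
      file = files, chrom = chrom, pos = pos, ref = refA, alt = altA,
      type = type, copies = copies, stringsAsFactors = FALSE)
  }
  addTruth <- function(chrom, pos, kind, subgenome, refA, altA, carriers,
                       destab_pos = NA_integer_, destab_type = NA_character_,
                       destab_alt = NA_character_, offset = NA_integer_,
                       satisfies = TRUE, note = "") {
    ep <- 2L * (n_sub - length(deletedSubs(chrom, pos)))
    if (kind %in% c("haplosnp_snpsnp", "haplosnp_indelsnp", "snp_in_insertion"))
      ep <- 2L   # destabilisation restricts hybridisation to one subgenome
    truth[[length(truth) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, kind = kind, subgenome = subgenome,
      ref = refA, alt = altA, carriers = paste(carriers, collapse = ";"),
      destab_pos = destab_pos, destab_type = destab_type,
      destab_alt = destab_alt, offset = offset, effective_ploidy = ep,
      in_deletion = length(deletedSubs(chrom, pos)) > 0, satisfies = satisfies,
      note = note, stringsAsFactors = FALSE)
  }
  carrierFiles <- function(carriers) file_ids[file_acc %in% carriers]

  ## --- fixed HSVs ------------------------------------------------------
  plantHsvSnp <- function(chrom, pos) {
    s <- pickSub(chrom, pos); if (is.na(s)) return(invisible())
    rb <- refBase(chrom, pos)
    alt <- sample(BASES[BASES != rb], 1)
    addObs(file_ids, chrom, pos, rb, alt, "snp", 2L)
    addTruth(chrom, pos, "hsv_snp", s, rb, alt, acc_ids)
    invisible(c(alt = alt))
  }
  plantHsvIndel <- function(chrom, pos, len = NULL, insertion = NA) {
    s <- pickSub(chrom, pos); if (is.na(s)) return(invisible())
    if (is.null(len)) len <- sample(4:6, 1)
    if (is.na(insertion)) insertion <- runif(1) < 0.5
    rb <- refBase(chrom, pos)
    if (insertion) {
      refA <- rb; altA <- paste0(rb, .randSeq(len)); type <- "ins"
    } else {
      refA <- refSeq(chrom, pos, pos + len); altA <- rb; type <- "del"
    }
    addObs(file_ids, chrom, pos, refA, altA, type, 2L)
    addTruth(chrom, pos, "hsv_indel", s, refA, altA, acc_ids)
    invisible(list(ref = refA, alt = altA, type = type, len = len))
  }
  sl <- take(counts[["hsv_snp"]])
  for (i in seq_len(nrow(sl))) plantHsvSnp(sl$chrom[i], sl$pos[i])
  sl <- take(counts[["hsv_indel"]])
  for (i in seq_len(nrow(sl))) plantHsvIndel(sl$chrom[i], sl$pos[i])

  ## --- segregating di-allelic marker SNPs ------------------------------
  sl <- take(counts[["diallelic_snp"]])
  for (i in seq_len(nrow(sl))) {
    chrom <- sl$chrom[i]; pos <- sl$pos[i]
    s <- pickSub(chrom, pos); if (is.na(s)) next
    rb <- refBase(chrom, pos)
    alt <- .safeAlt(rb, sample.int(100, 1))
    carriers <- pickCarriers()
    addObs(carrierFiles(carriers), chrom, pos, rb, alt, "snp", 2L)
    addTruth(chrom, pos, "diallelic_snp", s, rb, alt, carriers)
  }

  ## --- segregating marker indels (3-6 bp) ------------------------------
  sl <- take(counts[["indel"]])
  for (i in seq_len(nrow(sl))) {
    chrom <- sl$chrom[i]; pos <- sl$pos[i]
    s <- pickSub(chrom, pos); if (is.na(s)) next
    len <- sample(3:6, 1)
    rb <- refBase(chrom, pos)
    if (runif(1) < 0.5) {
      refA <- rb; altA <- paste0(rb, .randSeq(len)); type <- "ins"
    } else {
      refA <- refSeq(chrom, pos, pos + len); altA <- rb; type <- "del"
    }
    carriers <- pickCarriers()
    addObs(carrierFiles(carriers), chrom, pos, refA, altA, type, 2L)
    addTruth(chrom, pos, "indel", s, refA, altA, carriers)
  }

  ## --- multi-allelic sites: one segregating allele + one fixed allele --
  sl <- take(counts[["msnp"]])
  for (i in seq_len(nrow(sl))) {
    chrom <- sl$chrom[i]; pos <- sl$pos[i]
    s <- pickSub(chrom, pos); if (is.na(s)) next
    s2 <- pickSub(chrom, pos); if (is.na(s2)) next
    rb <- refBase(chrom, pos)
    alt1 <- .safeAlt(rb, sample.int(100, 1))         # marker allele
    alt2 <- sample(setdiff(BASES, c(rb, alt1)), 1)   # fixed background allele
    carriers <- pickCarriers()
    addObs(carrierFiles(carriers), chrom, pos, rb, alt1, "snp", 2L)
    addObs(file_ids, chrom, pos, rb, alt2, "snp", 2L)
    addTruth(chrom, pos, "msnp", s, rb, alt1, carriers,
             note = paste0("fixed_allele=", alt2))
  }

  ## --- haploSNPs -------------------------------------------------------
  sl <- take(counts[["haplosnp_snpsnp"]])
  for (i in seq_len(nrow(sl))) {
    chrom <- sl$chrom[i]; pos <- sl$pos[i]
    s <- pickSub(chrom, pos); if (is.na(s)) next
    off <- sample(1:6, 1) * sample(c(-1L, 1L), 1)
    dpos <- pos + off
    rb <- refBase(chrom, pos)
    alt <- .safeAlt(rb, sample.int(100, 1))
    db <- refBase(chrom, dpos)
    dalt <- sample(BASES[BASES != db], 1)
    carriers <- pickCarriers()
    addObs(carrierFiles(carriers), chrom, pos, rb, alt, "snp", 2L)
    addObs(file_ids, chrom, dpos, db, dalt, "snp", 2L)
    addTruth(chrom, pos, "haplosnp_snpsnp", s, rb, alt, carriers,
             destab_pos = dpos, destab_type = "snp", destab_alt = dalt,
             offset = abs(off))
    addTruth(chrom, dpos, "hsv_snp", s, db, dalt, acc_ids,
             note = "destabiliser")
  }

  sl <- take(counts[["haplosnp_indelsnp"]])
  for (i in seq_len(nrow(sl))) {
    chrom <- sl$chrom[i]; pos <- sl$pos[i]
    s <- pickSub(chrom, pos); if (is.na(s)) next
    len <- sample(4:6, 1)
    off <- sample(2:14, 1) * sample(c(-1L, 1L), 1)
    dpos <- pos + off
    rb <- refBase(chrom, pos)
    alt <- .safeAlt(rb, sample.int(100, 1))
    db <- refBase(chrom, dpos)
    ins <- runif(1) < 0.5
    # upstream deletions edit bases dpos+1..dpos+len; keep the marker base
    # itself unedited and the nearest edited base within 14 bp
    if (!ins && off < 0 && dpos + len >= pos) ins <- TRUE
    if (ins) {
      drefA <- db; daltA <- paste0(db, .randSeq(len)); dtype <- "ins"
    } else {
      drefA <- refSeq(chrom, dpos, dpos + len); daltA <- db; dtype <- "del"
    }
    carriers <- pickCarriers()
    addObs(carrierFiles(carriers), chrom, pos, rb, alt, "snp", 2L)
    addObs(file_ids, chrom, dpos, drefA, daltA, dtype, 2L)
    addTruth(chrom, pos, "haplosnp_indelsnp", s, rb, alt, carriers,
             destab_pos = dpos, destab_type = dtype, destab_alt = daltA,
             offset = abs(off))
    addTruth(chrom, dpos, "hsv_indel", s, drefA, daltA, acc_ids,
             note = "destabiliser")
  }

  ## --- SNP-in-insertion: all accessions carry a 3-6 bp insertion whose
  ## internal sequence differs at one base between carriers and the rest --
  sl <- take(counts[["snp_in_insertion"]])
  for (i in seq_len(nrow(sl))) {
    chrom <- sl$chrom[i]; pos <- sl$pos[i]
    s <- pickSub(chrom, pos); if (is.na(s)) next
    len <- sample(3:6, 1)
    inner <- strsplit(.randSeq(len), "")[[1]]
    at <- sample.int(len, 1)
    inner2 <- inner
    inner2[at] <- sample(BASES[BASES != inner[at]], 1)
    rb <- refBase(chrom, pos)
    alt_common <- paste0(rb, paste(inner, collapse = ""))
    alt_marker <- paste0(rb, paste(inner2, collapse = ""))
    carriers <- pickCarriers()
    noncar <- setdiff(acc_ids, carriers)
    addObs(carrierFiles(carriers), chrom, pos, rb, alt_marker, "ins", 2L)
    addObs(carrierFiles(noncar), chrom, pos, rb, alt_common, "ins", 2L)
    addTruth(chrom, pos, "snp_in_insertion", s, rb, alt_marker, carriers,
             destab_pos = pos, destab_type = "ins", destab_alt = alt_common,
             offset = at, note = paste0("insert_len=", len))
  }

  ## --- diploid outgroup heterozygous sites -----------------------------
  dip_cov <- 36
  dip <- list()
  sl <- take(counts[["diploid_snp"]])
  for (i in seq_len(nrow(sl))) {
    chrom <- sl$chrom[i]; pos <- sl$pos[i]
    rb <- refBase(chrom, pos)
    alt <- .safeAlt(rb, sample.int(100, 1))
    ao <- max(3L, rpois(1, dip_cov / 2))
    ro <- max(3L, rpois(1, dip_cov / 2))
    dip[[length(dip) + 1L]] <- data.frame(
      chrom = chrom, pos = pos, ref = rb, alt = alt, type = "snp",
      DP = ao + ro, RO = ro, AO = ao, stringsAsFactors = FALSE)
    addTruth(chrom, pos, "diploid_snp", NA_integer_, rb, alt, "F1D")
  }

  ## --- decoys: planted to FAIL one named filter each --------------------
  decoy_kinds <- c("decoy_flank", "decoy_lowpresence", "decoy_atgc",
                   "decoy_bigindel", "decoy_far_haplosnp")
  sl <- take(counts[["decoy"]])
  for (i in seq_len(nrow(sl))) {
    chrom <- sl$chrom[i]; pos <- sl$pos[i]
    kind <- decoy_kinds[1 + (i - 1) %% length(decoy_kinds)]
    rb <- refBase(chrom, pos)
    if (kind == "decoy_flank") {
      # otherwise-perfect marker with a second segregating variant 10 bp away
      alt <- .safeAlt(rb, sample.int(100, 1))
      carriers <- pickCarriers()
      addObs(carrierFiles(carriers), chrom, pos, rb, alt, "snp", 2L)
      nb <- pos + 10L
      nbase <- refBase(chrom, nb)
      nalt <- .safeAlt(nbase, sample.int(100, 1))
      nc <- pickCarriers()
      addObs(carrierFiles(nc), chrom, nb, nbase, nalt, "snp", 2L)
      addTruth(chrom, pos, kind, NA_integer_, rb, alt, carriers,
               satisfies = FALSE, note = "neighbour_at_+10")
      addTruth(chrom, nb, "decoy_neighbor", NA_integer_, nbase, nalt, nc,
               satisfies = FALSE, note = "neighbour_of_decoy_flank")
    } else if (kind == "decoy_lowpresence") {
      alt <- .safeAlt(rb, sample.int(100, 1))
      carriers <- acc_ids[sample(2:n_acc, 1)]  # single carrier, never acc01
      addObs(carrierFiles(carriers), chrom, pos, rb, alt, "snp", 2L)
      addTruth(chrom, pos, kind, NA_integer_, rb, alt, carriers,
               satisfies = FALSE, note = "present_in_1")
    } else if (kind == "decoy_atgc") {
      alt <- c(A = "T", T = "A", C = "G", G = "C")[[rb]]
      carriers <- pickCarriers()
      addObs(carrierFiles(carriers), chrom, pos, rb, alt, "snp", 2L)
      addTruth(chrom, pos, kind, NA_integer_, rb, alt, carriers,
               satisfies = FALSE, note = "AT_or_GC_pair")
    } else if (kind == "decoy_bigindel") {
      refA <- refSeq(chrom, pos, pos + 8L)
      carriers <- pickCarriers()
      addObs(carrierFiles(carriers), chrom, pos, refA, rb, "del", 2L)
      addTruth(chrom, pos, kind, NA_integer_, refA, rb, carriers,
               satisfies = FALSE, note = "8bp_indel")
    } else { # decoy_far_haplosnp: destabiliser SNP at offset 7 (> 6 bp rule)
      alt <- .safeAlt(rb, sample.int(100, 1))
      dpos <- pos + 7L
      db <- refBase(chrom, dpos)
      dalt <- sample(BASES[BASES != db], 1)
      carriers <- pickCarriers()
      addObs(carrierFiles(carriers), chrom, pos, rb, alt, "snp", 2L)
      addObs(file_ids, chrom, dpos, db, dalt, "snp", 2L)
      addTruth(chrom, pos, kind, NA_integer_, rb, alt, carriers,
               destab_pos = dpos, destab_type = "snp", destab_alt = dalt,
               offset = 7L, satisfies = FALSE, note = "offset_7_gt_6")
      addTruth(chrom, dpos, "hsv_snp", NA_integer_, db, dalt, acc_ids,
               note = "destabiliser_of_decoy")
    }
  }

  ## --- gene models: uniformly spaced two-exon genes --------------------
  genes <- .makeGeneModels(chroms, chr_len, config@gene_fraction)

  ## --- codon-site truth: third positions of proline codons with clean
  ## flanks relative to every planted variant -----------------------------
  truth_df <- do.call(rbind, truth)
  if (is.null(truth_df))
    truth_df <- data.frame(chrom = character(), pos = integer(),
                           kind = character(), subgenome = integer(),
                           ref = character(), alt = character(),
                           carriers = character(), destab_pos = integer(),
                           destab_type = character(), destab_alt = character(),
                           offset = integer(), effective_ploidy = integer(),
                           in_deletion = logical(), satisfies = logical(),
                           note = character(), stringsAsFactors = FALSE)
  codon <- .scanProlineThirdPositions(ref, genes)
  if (nrow(codon)) {
    # flank cleanliness is judged against the octoploid panel only (the
    # diploid sample's variants do not enter the codon pipeline's screen)
    planted <- truth_df[truth_df$kind != "diploid_snp", c("chrom", "pos")]
    clean <- vapply(seq_len(nrow(codon)), function(i) {
      same <- planted$chrom == codon$chrom[i]
      d <- abs(planted$pos[same] - codon$pos[i])
      !any(d >= 1 & d <= 24)   # a variant at the site itself is not a flank
    }, logical(1))
    truth_df <- rbind(truth_df, data.frame(
      chrom = codon$chrom, pos = codon$pos, kind = "codon_site",
      subgenome = NA_integer_, ref = codon$ref, alt = NA_character_,
      carriers = "", destab_pos = NA_integer_, destab_type = NA_character_,
      destab_alt = NA_character_, offset = NA_integer_,
      effective_ploidy = NA_integer_, in_deletion = FALSE,
      satisfies = clean, note = paste0("strand=", codon$strand),
      stringsAsFactors = FALSE))
  }

  ## --- read counts per file --------------------------------------------
  obs_df <- if (length(obs)) do.call(rbind, obs) else
    data.frame(file = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), type = character(),
               copies = integer(), stringsAsFactors = FALSE)
  vcfs <- setNames(vector("list", length(file_ids)), file_ids)
  for (f in file_ids) {
    rows <- obs_df[obs_df$file == f, , drop = FALSE]
    if (!nrow(rows)) {
      vcfs[[f]] <- data.frame(chrom = character(), pos = integer(),
                              ref = character(), alt = character(),
                              type = character(), DP = integer(),
                              RO = integer(), AO = integer(),
                              stringsAsFactors = FALSE)
      next
    }
    rows <- rows[order(rows$chrom, rows$pos, rows$alt), , drop = FALSE]
    lam <- cov[[f]] / (2 * n_sub)
    tot_copies <- vapply(seq_len(nrow(rows)), function(i)
      2L * (n_sub - length(deletedSubs(rows$chrom[i], rows$pos[i]))),
      integer(1))
    ao <- pmax(config@min_alt_reads,
               rpois(nrow(rows), rows$copies * lam))
    other <- rpois(nrow(rows), pmax(0, tot_copies - rows$copies) * lam)
    # multi-allelic sites: depth is shared, RO excludes all alt reads there
    key <- paste(rows$chrom, rows$pos)
    alt_sum <- tapply(ao, key, sum)[key]
    dp <- as.integer(alt_sum + other)
    ro <- as.integer(dp - alt_sum)
    vcfs[[f]] <- data.frame(chrom = rows$chrom, pos = rows$pos,
                            ref = rows$ref, alt = rows$alt, type = rows$type,
                            DP = dp, RO = ro, AO = as.integer(ao),
                            stringsAsFactors = FALSE)
  }
  dip_df <- if (length(dip)) {
    d <- do.call(rbind, dip); d[order(d$chrom, d$pos), ]
  } else data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), type = character(), DP = integer(),
                    RO = integer(), AO = integer(), stringsAsFactors = FALSE)

  o <- order(truth_df$chrom, truth_df$pos, truth_df$kind)
  truth_df <- truth_df[o, ]
  rownames(truth_df) <- NULL

  new("SyntheticPanel", reference = ref, genes = genes, vcfs = vcfs,
      diploid_vcf = dip_df, truth = truth_df, deletions = deletions,
      file_coverages = cov, file_accessions = file_acc, config = config)
}

# uniformly spaced two-exon genes; CDS length 798 (divisible by 3),
# alternating strand, frame 0
.makeGeneModels <- function(chroms, chr_len, gene_fraction) {
  if (gene_fraction <= 0)
    return(GenomicRanges::GRanges())
  g_len <- 898L   # exon1 1-399, intron 400-499, exon2 500-898
  period <- as.integer(ceiling(g_len / gene_fraction))
  out <- list()
  gid <- 0L
  for (i in seq_along(chroms)) {
    starts <- seq.int(101L, chr_len[i] - g_len - 100L, by = period)
    for (s in starts) {
      gid <- gid + 1L
      strand <- if (gid %% 2L) "+" else "-"
      id <- sprintf("gene%04d", gid)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chroms[i],
        start = c(s, s, s + 499L),
        end = c(s + g_len - 1L, s + 398L, s + g_len - 1L),
        type = c("gene", "CDS", "CDS"),
        strand = strand, gene = id, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$type <- df$type
  gr$gene <- df$gene
  # exon frame in transcription order: CDS pieces are 399 bp each, so the
  # second piece starts in frame 0 as well (399 %% 3 == 0)
  gr$phase <- ifelse(df$type == "CDS", 0L, NA_integer_)
  gr
}

# generator-side scan (independent of the discovery pipeline's scanner):
# genome coordinates of the third base of every proline codon (CCN) in CDS
.scanProlineThirdPositions <- function(ref, genes) {
  out <- list()
  if (!length(genes)) return(data.frame(chrom = character(), pos = integer(),
                                        ref = character(), strand = character(),
                                        stringsAsFactors = FALSE))
  cds <- genes[genes$type == "CDS"]
  for (g in unique(cds$gene)) {
    pieces <- cds[cds$gene == g]
    pieces <- pieces[order(GenomicRanges::start(pieces))]
    chrom <- as.character(GenomicRanges::seqnames(pieces))[1]
    strand <- as.character(GenomicRanges::strand(pieces))[1]
    pos_vec <- unlist(lapply(seq_along(pieces), function(i)
      seq.int(GenomicRanges::start(pieces)[i], GenomicRanges::end(pieces)[i])))
    seqv <- strsplit(as.character(Biostrings::subseq(
      rep(ref[chrom], length(pieces)),
      GenomicRanges::start(pieces), GenomicRanges::end(pieces))), "")
    seqv <- unlist(seqv)
    if (strand == "-") {
      pos_vec <- rev(pos_vec)
      seqv <- chartr("ACGT", "TGCA", rev(seqv))
    }
    n_codon <- length(seqv) %/% 3L
    for (k in seq_len(n_codon)) {
      i <- 3L * (k - 1L)
      if (seqv[i + 1L] == "C" && seqv[i + 2L] == "C") {
        p3 <- pos_vec[i + 3L]
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, pos = p3,
          ref = as.character(Biostrings::subseq(ref[[chrom]], p3, p3)),
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               strand = character(), stringsAsFactors = FALSE)
}

#' Simulate disomic-inheritance progeny genotypes
#'
#' Each progeny receives one allele drawn uniformly from each parent at
#' every marker; within the segregating subgenome the locus behaves exactly
#' like a diploid locus (full disomic inheritance). Genotypes are two-letter
#' strings over the alleles A, B and O, where O denotes the null allele
#' (no hybridisation signal): AA, AB, BB, AO, BO, OO.
#'
#' @param parent1,parent2 character vectors of parental genotypes per
#'   marker (recycled to a common length).
#' @param n_progeny number of progeny to draw.
#' @param seed integer seed.
#' @return list with `parents` (2-column matrix) and `progeny`
#'   (markers x progeny character matrix).
#' @examples
#' generatePedigree("AA", "BB", 4, seed = 1)$progeny  # all "AB"
#' @export
generatePedigree <- function(parent1, parent2, n_progeny, seed = 1L) {
  n <- max(length(parent1), length(parent2))
  parent1 <- rep_len(parent1, n); parent2 <- rep_len(parent2, n)
  gts <- c("AA", "AB", "BB", "AO", "BO", "OO")
  bad <- setdiff(unique(c(parent1, parent2)), gts)
  if (length(bad))
    stop("unknown genotype symbol(s): ", paste(bad, collapse = ", "))
  set.seed(as.integer(seed))
  splitAlleles <- function(g) strsplit(g, "")[[1]]
  progeny <- matrix("", n, n_progeny,
                    dimnames = list(paste0("m", seq_len(n)),
                                    paste0("p", seq_len(n_progeny))))
  for (i in seq_len(n)) {
    a1 <- splitAlleles(parent1[i]); a2 <- splitAlleles(parent2[i])
    pick1 <- a1[sample.int(2, n_progeny, replace = TRUE)]
    pick2 <- a2[sample.int(2, n_progeny, replace = TRUE)]
    progeny[i, ] <- paste0(pmin(pick1, pick2), pmax(pick1, pick2))
  }
  list(parents = cbind(parent1 = parent1, parent2 = parent2),
       progeny = progeny)
}

#' Simulate two-channel intensities for genotype clusters
#'
#' Deterministic cluster centres follow the linear model of
#' [ClusterCenterModel-class]: each hybridising homoeologous copy carrying
#' an A (B) allele adds `intensityA` (`intensityB`) to its channel, plus
#' background. The segregating subgenome contributes the two alleles of the
#' sample genotype; the remaining `effective_ploidy - 2` hybridising copies
#' are fixed for `background_allele`. Null alleles (O) contribute nothing,
#' so OO samples receive background-only signal in both channels.
#' Multiplicative log-normal noise `exp(N(0, noise_sd^2))` is applied per
#' channel; `noise_sd = 0` returns exact centres.
#'
#' @param genotypes markers x samples character matrix (AA/AB/BB/AO/BO/OO).
#' @param effective_ploidy integer vector per marker: number of
#'   homoeologous copies that hybridise to the probe (2 = full technical
#'   or biological ploidy reduction, 8 = unreduced octoploid).
#' @param model a [ClusterCenterModel-class].
#' @param noise_sd log-scale noise SD.
#' @param seed integer seed.
#' @param background_allele allele fixed in the non-segregating hybridising
#'   copies ("A" or "B").
#' @return data.frame with one row per marker x sample: marker, sample,
#'   genotype, A, B, contrast, size.
#' @examples
#' g <- matrix(c("AA", "AB", "BB"), 1, 3,
#'             dimnames = list("m1", c("s1", "s2", "s3")))
#' generateIntensities(g, effective_ploidy = 2L, noise_sd = 0)
#' @export
generateIntensities <- function(genotypes, effective_ploidy,
                                model = clusterCenterModel(), noise_sd = 0,
                                seed = 1L, background_allele = "B") {
  stopifnot(is.matrix(genotypes))
  validObject(model)
  effective_ploidy <- rep_len(as.integer(effective_ploidy), nrow(genotypes))
  if (any(effective_ploidy < 2L))
    stop("effective_ploidy must be >= 2")
  set.seed(as.integer(seed))
  out <- list()
  for (i in seq_len(nrow(genotypes))) {
    p <- effective_ploidy[i]
    for (j in seq_len(ncol(genotypes))) {
      al <- strsplit(genotypes[i, j], "")[[1]]
      nA <- sum(al == "A"); nB <- sum(al == "B")
      # a homozygous-null sample gives no hybridisation at all:
      # background-only signal in both channels
      if (genotypes[i, j] != "OO") {
        if (background_allele == "A") nA <- nA + (p - 2L)
        else nB <- nB + (p - 2L)
      }
      ab <- clusterCenter(nA, nB, model)
      if (noise_sd > 0)
        ab <- ab * exp(rnorm(2, 0, noise_sd))
      out[[length(out) + 1L]] <- data.frame(
        marker = rownames(genotypes)[i] %||% paste0("m", i),
        sample = colnames(genotypes)[j] %||% paste0("s", j),
        genotype = genotypes[i, j], A = ab[1], B = ab[2],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  cs <- contrastSize(res$A, res$B)
  res$contrast <- cs$contrast
  res$size <- cs$size
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a per-base read-depth track for one file
#'
#' Depth at each base is a Poisson draw with mean
#' `coverage * copies / (2 * n_subgenomes)`, where `copies` is the number of
#' homoeologous copies not removed by a deletion block at that base. A
#' block deleting k of 4 subgenomes therefore yields (1 - k/4) of the
#' outside depth in expectation.
#'
#' @param panel a [SyntheticPanel-class].
#' @param file file id (defaults to the first file).
#' @param seed integer seed.
#' @return named list of integer vectors, one per chromosome.
#' @export
simulateDepthTrack <- function(panel, file = NULL, seed = 1L) {
  stopifnot(is(panel, "SyntheticPanel"))
  if (is.null(file)) file <- names(panel@vcfs)[1]
  cov <- panel@file_coverages[[file]]
  n_sub <- panel@config@n_subgenomes
  set.seed(as.integer(seed))
  out <- list()
  for (chrom in names(panel@reference)) {
    L <- Biostrings::width(panel@reference[chrom])
    copies <- rep(2L * n_sub, L)
    del <- panel@deletions[panel@deletions$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(del))) {
      k <- length(strsplit(del$subgenomes[i], ",")[[1]])
      idx <- del$start[i]:del$end[i]
      copies[idx] <- pmax(0L, copies[idx] - 2L * k)
    }
    out[[chrom]] <- rpois(L, cov * copies / (2 * n_sub))
  }
  out
}
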