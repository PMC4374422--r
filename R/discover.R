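# empty candidate frame with the full column contract
.emptyCandidates <- function() {
  data.frame(category = character(), chrom = character(), pos = integer(),
             ref = character(), alleles = character(), n_alleles = integer(),
             atgc = logical(), strand = character(), destab_pos = integer(),
             destab_type = character(), destab_ref = character(),
             destab_alt = character(),
             offset = integer(), safety = character(),
             flank_up = character(), flank_down = character(),
             provenance = character(), stringsAsFactors = FALSE)
}

.candidateRow <- function(category, chrom, pos, ref, alleles, n_alleles,
                          atgc, strand, safety, provenance,
                          destab_pos = NA_integer_,
                          destab_type = NA_character_,
                          destab_ref = NA_character_,
                          destab_alt = NA_character_, offset = NA_integer_,
                          flank_up = NA_character_,
                          flank_down = NA_character_) {
  data.frame(category = category, chrom = chrom, pos = as.integer(pos),
             ref = ref, alleles = alleles, n_alleles = as.integer(n_alleles),
             atgc = atgc, strand = strand, destab_pos = as.integer(destab_pos),
             destab_type = destab_type, destab_ref = destab_ref,
             destab_alt = destab_alt,
             offset = as.integer(offset), safety = safety,
             flank_up = flank_up, flank_down = flank_down,
             provenance = provenance, stringsAsFactors = FALSE)
}

.bindCandidates <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (!length(lst)) return(.emptyCandidates())
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

.addFlanks <- function(cand, reference, up = 24L, down = 24L) {
  if (is.null(reference) || !nrow(cand)) return(cand)
  for (i in seq_len(nrow(cand))) {
    fl <- extractFlanks(reference, cand$chrom[i], cand$pos[i], up, down)
    cand$flank_up[i] <- fl$upstream
    cand$flank_down[i] <- fl$downstream
  }
  cand
}

# per-site allele inventory: site key -> variant row indices
.siteIndex <- function(table) {
  split(seq_len(nrow(table@variants)),
        paste(table@variants$chrom, table@variants$pos, sep = "\r"))
}

.indelLen <- function(ref, alt) abs(nchar(ref) - nchar(alt))

#' Discover di-allelic SNP candidates
#'
#' Emits coordinate sites where exactly two alleles (reference plus one
#' alternate SNP allele) are observed panel-wide and the alternate passes
#' the read-count, presence/absence, A/T-G/C, genic and BothSafe (24/24 bp)
#' filters.
#'
#' @param table a [PanelVariantTable-class].
#' @param config a [pipelineConfig()].
#' @param reference optional [Biostrings::DNAStringSet] for flank columns.
#' @param gene_models optional gene models for the genic filter.
#' @return candidate data.frame (one row per site; see package vignette
#'   for the column contract).
#' @export
discoverDiallelicSnps <- function(table, config = pipelineConfig(),
                                  reference = NULL, gene_models = NULL) {
  sites <- .siteIndex(table)
  pidx <- .positionIndex(table)
  v <- table@variants
  out <- list()
  for (s in sites) {
    if (length(s) != 1L) next                      # more than two alleles
    i <- s
    if (v$type[i] != "snp") next
    if (!readCountFilter(table, i, config)) next
    pa <- presenceAbsenceFilter(table, i, config)
    if (!pa$keep) next
    if (!atGcFilter(v$ref[i], v$alt[i])) next
    if (!genicFilter(v$chrom[i], v$pos[i], gene_models, config)) next
    saf <- flankSafety(table, v$chrom[i], v$pos[i], config$snp_up,
                       config$snp_down, pos_index = pidx)
    if (saf != "BothSafe") next
    out[[length(out) + 1L]] <- .candidateRow(
      "diallelic_snp", v$chrom[i], v$pos[i], v$ref[i],
      paste(v$ref[i], v$alt[i], sep = "/"), 2L, FALSE, "both", saf,
      sprintf("subpanel=%s;read_count;presence_absence;at_gc;genic=%s;flank=BothSafe",
              config$subpanel, config$genic_mode))
  }
  .addFlanks(.bindCandidates(out), reference, config$snp_up, config$snp_down)
}

#' Discover multi-allelic SNP (mSNP) candidates
#'
#' Emits sites with three or four observed alleles (two or three alternate
#' SNP alleles plus reference) where every alternate passes the read-count
#' filter, at least one alternate behaves as a segregating marker
#' (presence/absence), and the flanks are BothSafe or safe on one side.
#'
#' @inheritParams discoverDiallelicSnps
#' @export
discoverMsnps <- function(table, config = pipelineConfig(),
                          reference = NULL, gene_models = NULL) {
  sites <- .siteIndex(table)
  pidx <- .positionIndex(table)
  v <- table@variants
  out <- list()
  for (s in sites) {
    if (length(s) < 2L || length(s) > 3L) next
    if (!all(v$type[s] == "snp")) next
    if (!all(readCountFilter(table, s, config))) next
    pa <- presenceAbsenceFilter(table, s, config)
    if (!any(pa$keep)) next                       # no segregating allele
    if (!genicFilter(v$chrom[s[1]], v$pos[s[1]], gene_models, config)) next
    saf <- flankSafety(table, v$chrom[s[1]], v$pos[s[1]], config$snp_up,
                       config$snp_down, pos_index = pidx)
    if (saf == "Unsafe") next
    n_all <- length(s) + 1L
    out[[length(out) + 1L]] <- .candidateRow(
      "msnp", v$chrom[s[1]], v$pos[s[1]], v$ref[s[1]],
      paste(c(v$ref[s[1]], sort(v$alt[s])), collapse = "/"), n_all, FALSE,
      if (saf == "BothSafe") "both"
      else if (saf == "UpSafe-only") "forward" else "reverse",
      saf,
      sprintf("subpanel=%s;read_count;marker_allele;genic=%s;flank=%s%s",
              config$subpanel, config$genic_mode, saf,
              if (n_all == 4L) ";tetra" else ""))
  }
  .addFlanks(.bindCandidates(out), reference, config$snp_up, config$snp_down)
}

#' Discover di-allelic indel candidates
#'
#' Emits di-allelic indel sites of 3-6 bp whose summed read support
#' reaches the indel threshold, which satisfy Minimum Absence on the
#' filtration subpanel, and whose 24 bp upstream / 30 bp downstream
#' windows are free of other variants.
#'
#' @inheritParams discoverDiallelicSnps
#' @export
discoverIndels <- function(table, config = pipelineConfig(),
                           reference = NULL, gene_models = NULL) {
  sites <- .siteIndex(table)
  pidx <- .positionIndex(table)
  v <- table@variants
  out <- list()
  for (s in sites) {
    if (length(s) != 1L) next
    i <- s
    if (!v$type[i] %in% c("ins", "del")) next
    len <- .indelLen(v$ref[i], v$alt[i])
    if (len < config$indel_size_range[1] || len > config$indel_size_range[2]) next
    if (!readCountFilter(table, i, config)) next
    pa <- presenceAbsenceFilter(table, i, config, check_absence_only = TRUE)
    if (!pa$keep) next
    if (!genicFilter(v$chrom[i], v$pos[i], gene_models, config)) next
    saf <- flankSafety(table, v$chrom[i], v$pos[i], config$indel_up,
                       config$indel_down, pos_index = pidx)
    if (saf != "BothSafe") next
    atgc <- FALSE  # site-level A/T-G/C context flag set at design time
    out[[length(out) + 1L]] <- .candidateRow(
      "indel", v$chrom[i], v$pos[i], v$ref[i],
      paste(v$ref[i], v$alt[i], sep = "/"), 2L, atgc, "both", saf,
      sprintf("subpanel=%s;read_count;min_absence;size=%d;flank=BothSafe",
              config$subpanel, len))
  }
  .addFlanks(.bindCandidates(out), reference, config$indel_up,
             config$indel_down)
}

#' Discover ploidy-reducing haploSNP candidates
#'
#' Two-phase search: (1) destabilisation candidates are variants present
#' in every filtration-subpanel member (HSV-like); (2) marker candidates
#' are SNPs present in >= 2 and absent in >= 2 members passing the
#' read-count filter; (3) pairs obey the strategy's distance/containment
#' rule -- `snp_snp`: destabilising SNP within 6 bp of the marker;
#' `indel_snp`: destabilising 4-6 bp indel within 14 bp (offsets measured
#' to the indel's left-aligned position); `snp_in_insertion`: the marker
#' base sits inside a fixed 3-6 bp insertion whose sequence differs at
#' exactly one internal position between carriers and non-carriers;
#' (4) the 24 bp windows around the marker contain no variant other than
#' the destabiliser; (5) every file carrying the marker allele also
#' carries the critical destabilising form (accession-level coupling).
#'
#' SNP-SNP and indel-SNP sites are single-strand by construction: the
#' probe extends from the marker across the destabilisation site, so the
#' tiled strand is "reverse" for downstream destabilisers and "forward"
#' for upstream ones.
#'
#' @inheritParams discoverDiallelicSnps
#' @param strategy one of "snp_snp", "indel_snp", "snp_in_insertion".
#' @export
discoverHaploSnps <- function(table, config = pipelineConfig(),
                              strategy = c("snp_snp", "indel_snp",
                                           "snp_in_insertion"),
                              reference = NULL) {
  strategy <- match.arg(strategy)
  v <- table@variants
  files <- subpanel(table, config$subpanel)
  pres <- table@support[, files, drop = FALSE] > 0L
  n_sub_files <- length(files)
  pres_n <- rowSums(pres)
  pidx <- .positionIndex(table)

  if (strategy == "snp_in_insertion")
    return(.discoverSnpInInsertion(table, config, pres, pres_n, pidx,
                                   reference))

  ## phase 1: destabilisation candidates (present in ALL subpanel members)
  fixed <- pres_n == n_sub_files
  destab <- if (strategy == "snp_snp") {
    which(fixed & v$type == "snp")
  } else {
    len <- .indelLen(v$ref, v$alt)
    which(fixed & v$type %in% c("ins", "del") &
            len >= config$indelsnp_size_range[1] &
            len <= config$indelsnp_size_range[2])
  }
  max_off <- if (strategy == "snp_snp") config$snpsnp_max_offset
             else config$indelsnp_max_offset

  ## phase 2: marker SNP candidates
  rc <- readCountFilter(table, config = config)
  pa <- pres_n >= config$min_present &
    (n_sub_files - pres_n) >= config$min_absent
  markers <- which(v$type == "snp" & rc & pa)

  out <- list()
  for (i in markers) {
    near <- destab[v$chrom[destab] == v$chrom[i] &
                     abs(v$pos[destab] - v$pos[i]) >= 1L &
                     abs(v$pos[destab] - v$pos[i]) <= max_off]
    ## deletions spanning the marker base would remove it: exclude
    if (strategy == "indel_snp" && length(near)) {
      span <- v$type[near] == "del" &
        v$pos[near] < v$pos[i] &
        v$pos[near] + nchar(v$ref[near]) - 1L >= v$pos[i]
      near <- near[!span]
    }
    for (d in near) {
      ## phase 4: clean windows, destabiliser as the single exception
      saf <- flankSafety(table, v$chrom[i], v$pos[i], config$clean_window,
                         config$clean_window, exception_pos = v$pos[d],
                         pos_index = pidx)
      if (saf != "BothSafe") next
      ## phase 5: accession-level coupling
      mcar <- pres[i, ]
      dcar <- pres[d, ]
      if (!all(dcar[mcar])) next
      off <- abs(v$pos[d] - v$pos[i])
      strand <- if (v$pos[d] > v$pos[i]) "reverse" else "forward"
      out[[length(out) + 1L]] <- .candidateRow(
        paste0("haplosnp_", sub("_", "", strategy)),
        v$chrom[i], v$pos[i], v$ref[i],
        paste(v$ref[i], v$alt[i], sep = "/"), 2L,
        .isAtGcPair(v$ref[i], v$alt[i]), strand, saf,
        sprintf("subpanel=%s;read_count;presence_absence;coupled;window=%d",
                config$subpanel, config$clean_window),
        destab_pos = v$pos[d], destab_type = v$type[d],
        destab_ref = v$ref[d], destab_alt = v$alt[d], offset = off)
    }
  }
  .addFlanks(.bindCandidates(out), reference, config$clean_window,
             config$clean_window)
}

# SNP-in-insertion: sites with >= 2 fixed-length insertion alleles whose
# union covers every subpanel member and which differ at exactly one
# internal base; the variable base is the marker, the insertion the
# destabiliser
.discoverSnpInInsertion <- function(table, config, pres, pres_n, pidx,
                                    reference) {
  v <- table@variants
  n_sub_files <- ncol(pres)
  sites <- .siteIndex(table)
  out <- list()
  for (s in sites) {
    ins <- s[v$type[s] == "ins"]
    if (length(ins) < 2L) next
    for (len in unique(nchar(v$alt[ins]))) {
      grp <- ins[nchar(v$alt[ins]) == len]
      il <- len - 1L     # inserted bases beyond the anchor
      if (il < config$insertion_size_range[1] ||
          il > config$insertion_size_range[2]) next
      if (length(grp) != 2L) next
      a <- strsplit(v$alt[grp[1]], "")[[1]]
      b <- strsplit(v$alt[grp[2]], "")[[1]]
      diffs <- which(a != b)
      if (length(diffs) != 1L || diffs == 1L) next
      union_pres <- pres[grp[1], ] | pres[grp[2], ]
      if (sum(union_pres) != n_sub_files) next    # insertion must be fixed
      if (!all(readCountFilter(table, grp, config))) next
      ## the marker form is the rarer one; it must segregate
      ord <- grp[order(pres_n[grp])]
      marker <- ord[1]; common <- ord[2]
      if (pres_n[marker] < config$min_present ||
          (n_sub_files - pres_n[marker]) < config$min_absent) next
      ## coupling is intrinsic (the marker base rides on the insertion);
      ## clean windows around the shared coordinate
      saf <- flankSafety(table, v$chrom[marker], v$pos[marker],
                         config$clean_window, config$clean_window,
                         pos_index = pidx)
      if (saf != "BothSafe") next
      mb <- strsplit(v$alt[marker], "")[[1]][diffs]
      cb <- strsplit(v$alt[common], "")[[1]][diffs]
      out[[length(out) + 1L]] <- .candidateRow(
        "snp_in_insertion", v$chrom[marker], v$pos[marker], v$ref[marker],
        paste(v$alt[marker], v$alt[common], sep = "/"), 2L,
        .isAtGcPair(mb, cb), "both", saf,
        sprintf("subpanel=%s;read_count;presence_absence;contained;insert_len=%d",
                config$subpanel, il),
        destab_pos = v$pos[common], destab_type = "ins",
        destab_ref = v$ref[common], destab_alt = v$alt[common],
        offset = diffs - 1L)
    }
  }
  .addFlanks(.bindCandidates(out), reference, config$clean_window,
             config$clean_window)
}

#' Discover SNPs heterozygous in a diploid outgroup sample
#'
#' Emits SNP sites with read support for both alleles in the diploid
#' sample, alternate support reaching the SNP read-count threshold,
#' passing the A/T-G/C filter, and whose flanks are free of variants in
#' the union of the octoploid panel and the diploid sample itself.
#'
#' @param diploid_records record data.frame for the diploid sample (as
#'   from [readAccessionVcf()]).
#' @inheritParams discoverDiallelicSnps
#' @export
discoverDiploidParentSnps <- function(diploid_records, table,
                                      config = pipelineConfig(),
                                      reference = NULL) {
  d <- diploid_records
  pidx <- .positionIndex(table, extra = d)
  out <- list()
  for (i in seq_len(nrow(d))) {
    if (d$type[i] != "snp") next
    if (d$AO[i] < config$min_reads_snp || d$RO[i] < 1L) next
    if (!atGcFilter(d$ref[i], d$alt[i])) next
    other_here <- d$pos[d$chrom == d$chrom[i] & d$pos != d$pos[i]]
    saf <- flankSafety(table, d$chrom[i], d$pos[i], config$snp_up,
                       config$snp_down, pos_index = pidx)
    if (saf != "BothSafe") next
    out[[length(out) + 1L]] <- .candidateRow(
      "diploid_parent_snp", d$chrom[i], d$pos[i], d$ref[i],
      paste(d$ref[i], d$alt[i], sep = "/"), 2L, FALSE, "both", saf,
      "diploid_het;read_count;at_gc;flank=BothSafe(joint)")
  }
  .addFlanks(.bindCandidates(out), reference, config$snp_up, config$snp_down)
}

#' Find speculative codon-based candidate sites
#'
#' Mines coding sequence for proline codons (CC*) and emits the genome
#' coordinate of each codon's third (4-fold degenerate) position,
#' strand-corrected, where the flanks are BothSafe against the panel. No
#' variant evidence is required: these are speculative sites interrogated
#' to test whether polymorphism can be discovered by the array itself.
#' The speculative polymorphism is taken as reference base versus its
#' transition partner, which by construction never forms an A/T or G/C
#' pair.
#'
#' @param reference a [Biostrings::DNAStringSet].
#' @param gene_models [GenomicRanges::GRanges] with CDS rows carrying a
#'   `gene` column (exon order inferred from coordinates and strand).
#' @inheritParams discoverDiallelicSnps
#' @export
findCodonSites <- function(reference, gene_models, table,
                           config = pipelineConfig()) {
  pidx <- .positionIndex(table)
  cds <- gene_models[gene_models$type == "CDS"]
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  out <- list()
  for (g in unique(cds$gene)) {
    pieces <- cds[cds$gene == g]
    strand <- as.character(GenomicRanges::strand(pieces))[1]
    pieces <- pieces[order(GenomicRanges::start(pieces),
                           decreasing = (strand == "-"))]
    chrom <- as.character(GenomicRanges::seqnames(pieces))[1]
    piece_seq <- Biostrings::DNAStringSet(lapply(seq_along(pieces), function(i)
      Biostrings::subseq(reference[[chrom]],
                         GenomicRanges::start(pieces)[i],
                         GenomicRanges::end(pieces)[i])))
    if (strand == "-")
      piece_seq <- Biostrings::reverseComplement(piece_seq)
    tx <- unlist(piece_seq)
    genome_pos <- unlist(lapply(seq_along(pieces), function(i) {
      p <- seq.int(GenomicRanges::start(pieces)[i],
                   GenomicRanges::end(pieces)[i])
      if (strand == "-") rev(p) else p
    }))
    n_codon <- length(tx) %/% 3L
    if (n_codon == 0L) next
    cod <- as.character(Biostrings::codons(Biostrings::subseq(tx, 1L, n_codon * 3L)))
    pro <- which(substr(cod, 1, 2) == "CC")
    for (k in pro) {
      p3 <- genome_pos[3L * k]
      saf <- flankSafety(table, chrom, p3, config$snp_up, config$snp_down,
                         pos_index = pidx)
      if (saf != "BothSafe") next
      rb <- as.character(Biostrings::subseq(reference[[chrom]], p3, p3))
      out[[length(out) + 1L]] <- .candidateRow(
        "codon_based", chrom, p3, rb,
        paste(rb, transition[[rb]], sep = "/"), 2L, FALSE,
        if (strand == "-") "reverse" else "forward", saf,
        sprintf("proline_codon;gene=%s;speculative;flank=BothSafe", g))
    }
  }
  .bindCandidates(out)
}

# exact max-min subset of k points on a line: binary search over the
# achievable minimum gap with a greedy feasibility scan (the classic
# exact algorithm for this problem)
.maxMinSubset <- function(pos, k) {
  pos <- sort(pos)
  n <- length(pos)
  if (k >= n) return(pos)
  if (k == 1L) return(pos[1])
  gaps <- sort(unique(diff(pos)))
  cand_d <- sort(unique(unlist(lapply(seq_len(n - 1), function(i)
    pos[(i + 1):n] - pos[i]))))
  feasible <- function(d) {
    cnt <- 1L; last <- pos[1]
    for (p in pos[-1]) if (p - last >= d) { cnt <- cnt + 1L; last <- p }
    cnt >= k
  }
  lo <- 1L; hi <- length(cand_d)
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (feasible(cand_d[mid])) lo <- mid else hi <- mid - 1L
  }
  d <- if (feasible(cand_d[lo])) cand_d[lo] else 0L
  sel <- pos[1]; last <- pos[1]
  for (p in pos[-1]) {
    if (length(sel) == k) break
    if (p - last >= d) { sel <- c(sel, p); last <- p }
  }
  sel
}

#' Select a widely spaced, duplicate-free candidate subset
#'
#' First removes coordinate duplicates across categories using the array
#' inclusion priority (ploidy-reducing categories first, then remaining
#' octoploid categories, then diploid-derived, then codon-based), then
#' selects per chromosome the subset that maximises the minimum
#' inter-candidate spacing (computed exactly; ties broken toward lower
#' coordinates). The total target is apportioned across chromosomes by
#' candidate counts (largest remainder).
#'
#' @param candidates candidate data.frame (any mix of categories).
#' @param chrom_lengths named lengths (used only for apportioning order).
#' @param n_target total number of candidates to retain.
#' @param precedence category priority order for duplicate removal.
#' @return subset of `candidates`.
#' @export
spreadSelection <- function(candidates, chrom_lengths = NULL, n_target,
                            precedence = c("haplosnp_snpsnp",
                                           "haplosnp_indelsnp",
                                           "snp_in_insertion", "msnp",
                                           "diallelic_snp", "indel",
                                           "diploid_parent_snp",
                                           "codon_based")) {
  if (!nrow(candidates)) return(candidates)
  pr <- match(candidates$category, precedence)
  pr[is.na(pr)] <- length(precedence) + 1L
  o <- order(candidates$chrom, candidates$pos, pr)
  candidates <- candidates[o, ]
  dup <- duplicated(candidates[, c("chrom", "pos")])
  candidates <- candidates[!dup, ]
  if (n_target >= nrow(candidates)) return(candidates)
  per_chrom <- split(seq_len(nrow(candidates)), candidates$chrom)
  counts <- lengths(per_chrom)
  share <- n_target * counts / sum(counts)
  alloc <- floor(share)
  rem <- n_target - sum(alloc)
  if (rem > 0) {
    extra <- order(share - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1L
  }
  keep <- integer()
  for (ci in seq_along(per_chrom)) {
    idx <- per_chrom[[ci]]
    if (alloc[ci] == 0L) next
    sel_pos <- .maxMinSubset(candidates$pos[idx], alloc[ci])
    keep <- c(keep, idx[match(sel_pos, candidates$pos[idx])])
  }
  out <- candidates[sort(keep), ]
  rownames(out) <- NULL
  out
}

#' Run every discovery pipeline on a panel
#'
#' @inheritParams discoverDiallelicSnps
#' @param diploid_records optional diploid-sample records for the
#'   diploid-derived pipeline.
#' @param pipelines subset of pipelines to run.
#' @return named list of candidate data.frames plus `combined`.
#' @export
discoverAll <- function(table, config = pipelineConfig(), reference = NULL,
                        gene_models = NULL, diploid_records = NULL,
                        pipelines = c("snp", "msnp", "indel", "haplosnp",
                                      "diploid", "codon")) {
  res <- list()
  if ("snp" %in% pipelines)
    res$diallelic_snp <- discoverDiallelicSnps(table, config, reference,
                                               gene_models)
  if ("msnp" %in% pipelines)
    res$msnp <- discoverMsnps(table, config, reference, gene_models)
  if ("indel" %in% pipelines)
    res$indel <- discoverIndels(table, config, reference, gene_models)
  if ("haplosnp" %in% pipelines) {
    res$haplosnp_snpsnp <- discoverHaploSnps(table, config, "snp_snp",
                                             reference)
    res$haplosnp_indelsnp <- discoverHaploSnps(table, config, "indel_snp",
                                               reference)
    res$snp_in_insertion <- discoverHaploSnps(table, config,
                                              "snp_in_insertion", reference)
  }
  if ("diploid" %in% pipelines && !is.null(diploid_records))
    res$diploid_parent_snp <- discoverDiploidParentSnps(diploid_records,
                                                        table, config,
                                                        reference)
  if ("codon" %in% pipelines && !is.null(reference) &&
      !is.null(gene_models) && length(gene_models))
    res$codon_based <- findCodonSites(reference, gene_models, table, config)
  res$combined <- .bindCandidates(res)
  res
}

#' Write candidates as TSV and BED
#'
#' @param candidates candidate data.frame.
#' @param tsv,bed output paths (either may be NULL).
#' @return invisibly, the candidate frame.
#' @export
writeCandidates <- function(candidates, tsv = NULL, bed = NULL) {
  if (!is.null(tsv))
    write.table(candidates, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed) && nrow(candidates))
    writeLines(sprintf("%s\t%d\t%d\t%s", candidates$chrom,
                       candidates$pos - 1L, candidates$pos,
                       paste(candidates$category, candidates$alleles,
                             sep = "|")), bed)
  invisible(candidates)
}
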