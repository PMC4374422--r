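#' Panel configuration for loading per-accession VCFs
#'
#' Maps VCF files to accessions and defines the coverage-based filtration
#' subpanels: HD16 contains files at or above `hd16_min` mean coverage and
#' HD20 those at or above `hd20_min` (so HD20 is a subset of HD16). An
#' accession may contribute more than one file; presence/absence is counted
#' per file.
#'
#' @param files character vector of file ids.
#' @param accessions character vector mapping each file to its accession.
#' @param coverage numeric mean coverage per file.
#' @param hd16_min,hd20_min coverage thresholds for the subpanels.
#' @param diploid_file optional file id of the diploid outgroup VCF.
#' @return a list with class "panelConfig".
#' @export
panelConfig <- function(files, accessions = files, coverage = NULL,
                        hd16_min = 16, hd20_min = 20, diploid_file = NULL) {
  stopifnot(length(files) == length(accessions))
  if (is.null(coverage)) coverage <- rep(Inf, length(files))
  structure(list(files = files, accessions = setNames(accessions, files),
                 coverage = setNames(coverage, files),
                 subpanels = list(GDP = files,
                                  HD16 = files[coverage >= hd16_min],
                                  HD20 = files[coverage >= hd20_min]),
                 diploid_file = diploid_file),
            class = "panelConfig")
}

# left-aligned minimal representation of one VCF record: trim the shared
# suffix, then the shared prefix beyond the anchor base, adjusting pos
.normalizeVariant <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

.variantType <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == la & lr == 1L, "snp", ifelse(la > lr, "ins", "del"))
}

#' Read one per-accession VCF into a record data.frame
#'
#' Multi-allelic records are decomposed into one row per alternate allele
#' and indels are normalised to their left-aligned minimal representation.
#' Parsing is delegated to \pkg{vcfR}; per-sample DP/RO/AO fields carry the
#' read observations.
#'
#' @param path VCF file path.
#' @return data.frame(chrom, pos, ref, alt, type, DP, RO, AO).
#' @export
readAccessionVcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF in ", path, ": ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(fix) == 0)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), type = character(), DP = integer(),
                      RO = integer(), AO = integer(), stringsAsFactors = FALSE))
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")))
  ro <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "RO")))
  ao_raw <- vcfR::extract.gt(v, element = "AO")
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    aos <- suppressWarnings(as.integer(strsplit(ao_raw[i], ",", fixed = TRUE)[[1]]))
    aos <- rep_len(aos, length(alts))
    for (k in seq_along(alts)) {
      nv <- .normalizeVariant(as.integer(fix[i, "POS"]), fix[i, "REF"], alts[k])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = nv$pos, ref = nv$ref, alt = nv$alt,
        type = .variantType(nv$ref, nv$alt), DP = dp[i], RO = ro[i],
        AO = aos[k], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  dup <- duplicated(out[, c("chrom", "pos", "alt")])
  if (any(dup))
    stop("duplicate (coordinate, alt) record in ", path, " at ",
         out$chrom[dup][1], ":", out$pos[dup][1])
  rownames(out) <- NULL
  out
}

#' Build the union variant table from per-accession record sets
#'
#' @param vcf_list named list of record data.frames (as from
#'   [readAccessionVcf()] or the `vcfs` slot of a [SyntheticPanel-class]).
#' @param config a [panelConfig()].
#' @return a [PanelVariantTable-class].
#' @export
panelVariantTable <- function(vcf_list, config) {
  stopifnot(inherits(config, "panelConfig"))
  missing_files <- setdiff(config$files, names(vcf_list))
  if (length(missing_files))
    stop("no records supplied for file(s): ", paste(missing_files, collapse = ", "))
  all_rec <- do.call(rbind, lapply(config$files, function(f) {
    d <- vcf_list[[f]]
    if (nrow(d)) cbind(file = f, d, stringsAsFactors = FALSE) else NULL
  }))
  if (is.null(all_rec) || nrow(all_rec) == 0) {
    warning("no variant records in any input file; returning an empty table")
    variants <- data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           type = character(), stringsAsFactors = FALSE)
    m <- matrix(0L, 0, length(config$files),
                dimnames = list(NULL, config$files))
    return(new("PanelVariantTable", variants = variants, support = m,
               depth = m, files = config$files,
               accessions = config$accessions, subpanels = config$subpanels))
  }
  key <- paste(all_rec$chrom, all_rec$pos, all_rec$alt, sep = "\r")
  uk <- !duplicated(key)
  variants <- all_rec[uk, c("chrom", "pos", "ref", "alt", "type")]
  o <- order(variants$chrom, variants$pos, variants$alt)
  variants <- variants[o, ]
  rownames(variants) <- NULL
  vkey <- paste(variants$chrom, variants$pos, variants$alt, sep = "\r")
  support <- matrix(0L, nrow(variants), length(config$files),
                    dimnames = list(NULL, config$files))
  depth <- support
  ri <- match(key, vkey)
  ci <- match(all_rec$file, config$files)
  support[cbind(ri, ci)] <- all_rec$AO
  depth[cbind(ri, ci)] <- all_rec$DP
  depth <- pmax(depth, support)
  new("PanelVariantTable", variants = variants, support = support,
      depth = depth, files = config$files, accessions = config$accessions,
      subpanels = config$subpanels)
}

#' Load per-accession VCF files into a panel variant table
#'
#' @param vcf_paths named character vector of VCF paths; names are file ids
#'   matching `config$files`.
#' @param config a [panelConfig()].
#' @return a [PanelVariantTable-class].
#' @export
loadPanel <- function(vcf_paths, config) {
  recs <- lapply(vcf_paths, readAccessionVcf)
  names(recs) <- names(vcf_paths)
  panelVariantTable(recs, config)
}

.vcfHeader <- function(reference_lengths, sample) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(reference_lengths),
            reference_lengths),
    "##INFO=<ID=TYPE,Number=A,Type=String,Description=\"Variant type: snp, ins or del\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth at site\">",
    "##FORMAT=<ID=RO,Number=1,Type=Integer,Description=\"Reference-supporting reads\">",
    "##FORMAT=<ID=AO,Number=A,Type=Integer,Description=\"Alternate-supporting reads\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
}

.writeVcfRecords <- function(df, path, reference_lengths, sample) {
  lines <- .vcfHeader(reference_lengths, sample)
  if (nrow(df)) {
    df <- df[order(df$chrom, df$pos, df$alt), , drop = FALSE]
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t50\t.\tTYPE=%s\tDP:RO:AO\t%d:%d:%d",
                              df$chrom, df$pos, df$ref, df$alt, df$type,
                              df$DP, df$RO, df$AO))
  }
  writeLines(lines, path)
}

#' Write a synthetic panel to disk
#'
#' Emits reference FASTA, gene-model GFF3, one VCF v4.2 per file, the
#' diploid outgroup VCF and the ground-truth TSV. Deterministic: the same
#' panel object always produces byte-identical files.
#'
#' @param panel a [SyntheticPanel-class].
#' @param dir output directory (created if absent).
#' @return invisibly, a named list of written paths.
#' @export
writePanel <- function(panel, dir) {
  stopifnot(is(panel, "SyntheticPanel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref_path <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(panel@reference, ref_path, width = 80L)
  gff_path <- file.path(dir, "genes.gff3")
  .writeGff3(panel@genes, gff_path)
  lens <- setNames(Biostrings::width(panel@reference), names(panel@reference))
  vcf_paths <- character()
  for (f in names(panel@vcfs)) {
    p <- file.path(dir, paste0(f, ".vcf"))
    .writeVcfRecords(panel@vcfs[[f]], p, lens, f)
    vcf_paths[f] <- p
  }
  dip_path <- file.path(dir, "diploid_F1D.vcf")
  .writeVcfRecords(panel@diploid_vcf, dip_path, lens, "F1D")
  truth_path <- file.path(dir, "truth.tsv")
  write.table(panel@truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(reference = ref_path, gff = gff_path, vcfs = vcf_paths,
                 diploid = dip_path, truth = truth_path))
}

.writeGff3 <- function(gr, path) {
  lines <- "##gff-version 3"
  if (length(gr)) {
    attr_col <- ifelse(gr$type == "gene",
                       sprintf("ID=%s", gr$gene),
                       sprintf("Parent=%s", gr$gene))
    phase <- ifelse(is.na(gr$phase), ".", as.character(gr$phase))
    lines <- c(lines, sprintf("%s\tpolyArray\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                              as.character(GenomicRanges::seqnames(gr)),
                              gr$type, GenomicRanges::start(gr),
                              GenomicRanges::end(gr),
                              as.character(GenomicRanges::strand(gr)),
                              phase, attr_col))
  }
  writeLines(lines, path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 file.
#' @return a [GenomicRanges::GRanges] with columns type, gene, phase.
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  id <- as.character(gr$ID)
  parent <- vapply(gr$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, "")
  gene <- ifelse(is.na(parent) | parent == "", id, parent)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::ranges(gr),
                                strand = GenomicRanges::strand(gr))
  out$type <- as.character(gr$type)
  out$gene <- gene
  ph <- gr$phase
  out$phase <- if (is.null(ph)) NA_integer_ else as.integer(as.character(ph))
  out
}

#' Write back a panel variant table as per-accession VCFs
#'
#' Inverse of [loadPanel()]: each file's records are reconstructed from
#' the support/depth matrices (a record is emitted wherever the file has at
#' least one supporting read). Reloading the written files yields an
#' identical table.
#'
#' @param table a [PanelVariantTable-class].
#' @param dir output directory.
#' @param reference_lengths named integer vector of contig lengths for the
#'   VCF header.
#' @return invisibly, named vector of written paths.
#' @export
writePanelVcfs <- function(table, dir, reference_lengths) {
  stopifnot(is(table, "PanelVariantTable"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- table@variants
  key <- paste(v$chrom, v$pos)
  paths <- character()
  for (j in seq_along(table@files)) {
    f <- table@files[j]
    idx <- which(table@support[, j] > 0L)
    ao <- table@support[idx, j]
    dp <- table@depth[idx, j]
    alt_sum <- if (length(idx)) tapply(ao, key[idx], sum)[key[idx]] else integer()
    df <- data.frame(chrom = v$chrom[idx], pos = v$pos[idx], ref = v$ref[idx],
                     alt = v$alt[idx], type = v$type[idx], DP = dp,
                     RO = pmax(0L, as.integer(dp - alt_sum)), AO = ao,
                     stringsAsFactors = FALSE)
    p <- file.path(dir, paste0(f, ".vcf"))
    .writeVcfRecords(df, p, reference_lengths, f)
    paths[f] <- p
  }
  invisible(paths)
}

#' Turn a synthetic panel directly into a variant table
#'
#' In-memory equivalent of [writePanel()] + [loadPanel()].
#'
#' @param panel a [SyntheticPanel-class].
#' @return a [PanelVariantTable-class].
#' @export
makePanelTable <- function(panel) {
  stopifnot(is(panel, "SyntheticPanel"))
  cfg <- panelConfig(files = names(panel@vcfs),
                     accessions = unname(panel@file_accessions),
                     coverage = unname(panel@file_coverages))
  panelVariantTable(panel@vcfs, cfg)
}

#' Extract reference flanks around a site
#'
#' Returns the exact reference substrings upstream and downstream of the
#' coordinate, truncated (and flagged) at contig edges.
#'
#' @param reference a [Biostrings::DNAStringSet].
#' @param chrom contig name.
#' @param pos 1-based coordinate.
#' @param up_len,down_len flank lengths in bp (>= 0).
#' @return list(upstream, downstream, up_truncated, down_truncated).
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAC"))
#' extractFlanks(ref, "chr1", 5, 3, 3)
#' @export
extractFlanks <- function(reference, chrom, pos, up_len = 24L,
                          down_len = 24L) {
  if (!chrom %in% names(reference))
    stop("unknown contig: ", chrom)
  stopifnot(up_len >= 0, down_len >= 0)
  L <- Biostrings::width(reference[chrom])
  if (pos < 1 || pos > L)
    stop("coordinate ", pos, " outside contig ", chrom, " (length ", L, ")")
  u_start <- max(1L, pos - up_len)
  d_end <- min(L, pos + down_len)
  up <- if (pos == 1L) "" else
    as.character(Biostrings::subseq(reference[[chrom]], u_start, pos - 1L))
  down <- if (pos == L) "" else
    as.character(Biostrings::subseq(reference[[chrom]], pos + 1L, d_end))
  list(upstream = up, downstream = down,
       up_truncated = nchar(up) < up_len,
       down_truncated = nchar(down) < down_len)
}

#' Per-gene mean read depth and its unit-binned histogram
#'
#' Computes the mean of the per-base depths over each gene's extent, and a
#' histogram of gene means binned in unit increments from 0 to 150; values
#' of 150 or more are clipped into the final bin.
#'
#' @param depths named list of per-base integer depth vectors, one per
#'   chromosome (as from [simulateDepthTrack()]).
#' @param gene_models [GenomicRanges::GRanges] with a `type` column; rows
#'   with type "gene" define the extents.
#' @return list(means = named numeric per gene,
#'   histogram = data.frame(bin, count)) where `bin` is the lower edge.
#' @export
geneReadDepthProfile <- function(depths, gene_models) {
  genes <- gene_models[gene_models$type == "gene"]
  means <- setNames(numeric(length(genes)), genes$gene)
  for (i in seq_along(genes)) {
    chrom <- as.character(GenomicRanges::seqnames(genes))[i]
    if (!chrom %in% names(depths))
      stop("no depth track for contig ", chrom)
    s <- GenomicRanges::start(genes)[i]; e <- GenomicRanges::end(genes)[i]
    if (s < 1 || e > length(depths[[chrom]]))
      stop("gene ", genes$gene[i], " outside reference bounds")
    means[i] <- mean(depths[[chrom]][s:e])
  }
  bin <- pmin(floor(means), 150)
  hist_df <- data.frame(bin = 0:150,
                        count = as.integer(table(factor(bin, levels = 0:150))))
  list(means = means, histogram = hist_df)
}
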