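# shared fixture builders (all in code; nothing on disk)

# tiny variant table from explicit per-file observations
toyPanel <- function(obs, files = NULL, coverage = NULL) {
  if (is.null(files)) files <- sort(unique(obs$file))
  if (is.null(obs$type)) obs$type <- polyArray:::.variantType(obs$ref, obs$alt)
  if (is.null(obs$DP)) obs$DP <- obs$AO + 10L
  vcfs <- lapply(files, function(f) {
    d <- obs[obs$file == f, c("chrom", "pos", "ref", "alt", "type", "DP", "AO")]
    d$RO <- d$DP - d$AO
    d[, c("chrom", "pos", "ref", "alt", "type", "DP", "RO", "AO")]
  })
  names(vcfs) <- files
  panelVariantTable(vcfs, panelConfig(files, coverage = coverage))
}

# one SNP observation in each of `carrier` files, AO reads each
snpObs <- function(files, chrom = "chr1", pos, ref = "A", alt = "C",
                   AO = 5L) {
  data.frame(file = files, chrom = chrom, pos = pos, ref = ref, alt = alt,
             AO = AO, stringsAsFactors = FALSE)
}

# default 8-file panel ids
F8 <- sprintf("f%02d", 1:8)

smallPanelCached <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generatePanel(simConfig(seed = 42, ref_length = 60000L,
                                        n_chromosomes = 1L))
    cache
  }
})
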