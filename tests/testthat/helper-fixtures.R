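# shared fixtures, all generated in code

toyLig <- function() ligandSpec("OTA", "C4", "OTA")

toyComplex <- function(n = 30, seed = 3) buildToyComplex(n, toyLig(), seed)

# minimal PDB text written directly, for parser contract tests
writePdbLines <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

atomLine <- function(serial, name, resName, resSeq, x, y, z,
                     record = "ATOM", element = substr(name, 1, 1),
                     chain = "A") {
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, name, resName, chain, resSeq, x, y, z, element)
}

# batch-means standard error of a series mean (batches long relative to
# the OU decorrelation time, so batch means are near-independent)
batchSE <- function(v, nBatches = 50) {
  n <- length(v)
  size <- floor(n / nBatches)
  bm <- vapply(seq_len(nBatches),
               function(b) mean(v[((b - 1) * size + 1):(b * size)]),
               numeric(1))
  stats::sd(bm) / sqrt(nBatches)
}

numericPresets <- function() {
  Filter(function(p) is.na(p@ou@switchTPs), scenarioPresets())
}

randomSeq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                 "F","P","S","T","W","Y","V"), n, replace = TRUE),
        collapse = "")
}
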