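# Independent oracles, written without reference to the package
# internals they check.

# tabular-method numerator relationship matrix (dense), independent of
# the package's pedigree code: works on integer parent vectors
oracle_tabular_A <- function(sire, dam) {
  n <- length(sire)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
    if (i > 1) for (j in 1:(i - 1)) {
      v <- 0
      if (s > 0) v <- v + 0.5 * A[j, s]
      if (d > 0) v <- v + 0.5 * A[j, d]
      A[i, j] <- A[j, i] <- v
    }
  }
  A
}

# random valid pedigree as a data.frame (ids shuffled so sorting is
# exercised); parents always older than offspring
random_pedigree_df <- function(n, n_founders = max(4L, n %/% 4L)) {
  sex <- rep(c("M", "F"), length.out = n)
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    males <- which(sex[1:(i - 1)] == "M")
    females <- which(sex[1:(i - 1)] == "F")
    if (length(males) && runif(1) < 0.85) {
      sire[i] <- as.character(sample(males, 1))
    }
    if (length(females) && runif(1) < 0.85) {
      dam[i] <- as.character(sample(females, 1))
    }
  }
  df <- data.frame(individual = as.character(1:n), sire = sire,
                   dam = dam, sex = sex, stringsAsFactors = FALSE)
  df[sample.int(n), ]
}

# tiny phased genotype object built directly (bypassing file IO)
toy_phased <- function(H, chrom = "1", spacing = 1000L) {
  m <- ncol(H)
  map <- marker_map(sprintf("m%02d", 1:m), rep(chrom, m),
                    (1:m) * spacing)
  ids <- sprintf("i%02d", seq_len(nrow(H) / 2))
  phased_genotypes(ids, map, H)
}

# write a small phased VCF fixture; returns the path
write_vcf_fixture <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf3x5 <- function() {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "m1", "A", "C", ".", "PASS", ".", "GT",
          "0|0", "0|1", "1|1", sep = "\t"),
    paste("1", "200", "m2", "G", "T", ".", "PASS", ".", "GT",
          "0|1", "1|0", "0|0", sep = "\t"),
    paste("1", "300", "m3", "A", "G", ".", "PASS", ".", "GT",
          "1|1", "0|0", "0|1", sep = "\t"),
    paste("2", "100", "m4", "C", "T", ".", "PASS", ".", "GT",
          "0|0", "0|0", "1|0", sep = "\t"),
    paste("2", "250", "m5", "T", "A", ".", "PASS", ".", "GT",
          "0|1", "1|1", "0|0", sep = "\t"))
}
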