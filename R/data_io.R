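#' Marker map
#'
#' A marker map describes the SNP content of a linear genome assembly:
#' marker identifier, autosome label, 1-based physical position and the two
#' allele codes. Positions must be strictly increasing within a chromosome
#' and marker identifiers unique; all downstream interval logic (window
#' construction, co-location) treats positions as 1-based inclusive.
#'
#' @param marker_id character vector of unique marker names
#' @param chrom chromosome labels (autosome numbers)
#' @param pos integer 1-based physical positions
#' @param ref,alt allele codes (defaults "A"/"B")
#' @return a `data.table` of class `marker_map` with columns
#'   `marker_id`, `chrom`, `pos`, `ref`, `alt`
#' @export
marker_map <- function(marker_id, chrom, pos, ref = "A", alt = "B") {
  map <- data.table(
    marker_id = as.character(marker_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = rep_len(as.character(ref), length(marker_id)),
    alt = rep_len(as.character(alt), length(marker_id))
  )
  validate_marker_map(map)
  setattr(map, "class", c("marker_map", class(map)))
  map[]
}

validate_marker_map <- function(map) {
  if (anyDuplicated(map$marker_id)) {
    stop("marker_map: duplicated marker_id(s): ",
         paste(head(unique(map$marker_id[duplicated(map$marker_id)]), 5),
               collapse = ", "), call. = FALSE)
  }
  bad <- map[, .(ok = all(diff(pos) > 0)), by = chrom][ok == FALSE]
  if (nrow(bad)) {
    stop("marker_map: positions not strictly increasing on chromosome(s): ",
         paste(bad$chrom, collapse = ", "), call. = FALSE)
  }
  if (anyNA(map$pos) || any(map$pos < 1L)) {
    stop("marker_map: positions must be positive integers", call. = FALSE)
  }
  invisible(map)
}

#' Phased genotypes
#'
#' Container for phased genotypes: an ordered set of individuals, a
#' [marker_map()], and a haplotype matrix with two rows per individual
#' (suffixes `_A` and `_B`) over the map's markers. Allele coding is 0 =
#' reference, 1 = alternative, `NA` = missing.
#'
#' @param ids character vector of individual ids
#' @param map a [marker_map()]
#' @param H integer matrix, `2 * length(ids)` rows by `nrow(map)` columns;
#'   rows must be ordered `id1_A, id1_B, id2_A, ...`
#' @return an object of class `phased_genotypes`
#' @export
phased_genotypes <- function(ids, map, H) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("phased_genotypes: duplicated individual ids",
                               call. = FALSE)
  validate_marker_map(map)
  H <- as.matrix(H)
  storage.mode(H) <- "integer"
  if (nrow(H) != 2L * length(ids)) {
    stop("phased_genotypes: H must have two rows per individual",
         call. = FALSE)
  }
  if (ncol(H) != nrow(map)) {
    stop("phased_genotypes: H columns must match marker map", call. = FALSE)
  }
  if (any(H[!is.na(H)] %notin% c(0L, 1L))) {
    stop("phased_genotypes: allele codes must be 0, 1 or NA", call. = FALSE)
  }
  rownames(H) <- paste0(rep(ids, each = 2L), c("_A", "_B"))
  colnames(H) <- map$marker_id
  structure(list(ids = ids, map = map, H = H), class = "phased_genotypes")
}

`%notin%` <- function(x, table) !(x %in% table)

#' @export
print.phased_genotypes <- function(x, ...) {
  cat("phased_genotypes:", length(x$ids), "individuals,",
      nrow(x$map), "markers on", length(unique(x$map$chrom)),
      "chromosome(s);", sum(is.na(x$H)), "missing alleles\n")
  invisible(x)
}

#' Dosage matrix from phased genotypes
#'
#' Collapses the two haplotypes per individual into an alt-allele dosage
#' (0/1/2) matrix, `NA` when either allele is missing.
#'
#' @param pg a [phased_genotypes()] object
#' @return numeric matrix, individuals x markers
#' @export
dosage_matrix <- function(pg) {
  n <- length(pg$ids)
  a <- pg$H[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  b <- pg$H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  d <- a + b
  rownames(d) <- pg$ids
  d
}

#' Read phased genotypes
#'
#' Reads phased genotypes from either a phased VCF (GT field with `|`
#' separators; any `/`-separated genotype is rejected as unphased) or the
#' package's haplotype-matrix TSV dialect: one header line of marker ids,
#' then two rows per individual with ids suffixed `_A` and `_B`. The TSV
#' dialect carries no map metadata, so a sidecar file `<path>.map` (TSV
#' with columns marker_id, chrom, pos, ref, alt) is required alongside it.
#'
#' @param path input file
#' @param format one of `"phased-vcf"`, `"hapmatrix-tsv"`
#' @return a [phased_genotypes()] object
#' @export
read_phased_genotypes <- function(path,
                                  format = c("phased-vcf", "hapmatrix-tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         "phased-vcf" = read_phased_vcf(path),
         "hapmatrix-tsv" = read_hapmatrix(path))
}

read_phased_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1L) {
    stop("parse error in ", path, ": no #CHROM header line", call. = FALSE)
  }
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L) {
    stop("parse error in ", path, " line ", hdr, ": no sample columns",
         call. = FALSE)
  }
  ids <- cols[-(1:9)]
  body_idx <- which(seq_along(lines) > hdr & !startsWith(lines, "#") &
                      nzchar(lines))
  nmark <- length(body_idx)
  chrom <- character(nmark); pos <- integer(nmark)
  mid <- character(nmark); ref <- character(nmark); alt <- character(nmark)
  H <- matrix(NA_integer_, nrow = 2L * length(ids), ncol = nmark)
  for (k in seq_along(body_idx)) {
    ln <- body_idx[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L + length(ids)) {
      stop("parse error in ", path, " line ", ln, ": expected ",
           9L + length(ids), " fields, found ", length(f), call. = FALSE)
    }
    if (!startsWith(f[9], "GT")) {
      stop("parse error in ", path, " line ", ln,
           ": FORMAT must begin with GT", call. = FALSE)
    }
    chrom[k] <- f[1]
    pos[k] <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos[k])) {
      stop("parse error in ", path, " line ", ln, ": bad POS '", f[2], "'",
           call. = FALSE)
    }
    mid[k] <- if (f[3] == ".") paste0(f[1], "_", f[2]) else f[3]
    ref[k] <- f[4]; alt[k] <- f[5]
    gt <- sub(":.*$", "", f[-(1:9)])
    if (any(grepl("/", gt, fixed = TRUE))) {
      stop("phase error in ", path, " line ", ln,
           ": unphased genotype(s) '",
           gt[grepl("/", gt, fixed = TRUE)][1], "'", call. = FALSE)
    }
    ok <- grepl("^[0-9.]\\|[0-9.]$", gt)
    if (!all(ok)) {
      stop("parse error in ", path, " line ", ln, ": bad GT '",
           gt[!ok][1], "'", call. = FALSE)
    }
    a1 <- substr(gt, 1L, 1L); a2 <- substr(gt, 3L, 3L)
    conv <- function(a) ifelse(a == ".", NA_integer_, as.integer(a))
    v1 <- conv(a1); v2 <- conv(a2)
    if (any(stats::na.omit(c(v1, v2)) > 1L)) {
      stop("parse error in ", path, " line ", ln,
           ": only biallelic records supported", call. = FALSE)
    }
    H[seq(1L, nrow(H), 2L), k] <- v1
    H[seq(2L, nrow(H), 2L), k] <- v2
  }
  map <- marker_map(mid, chrom, pos, ref, alt)
  phased_genotypes(ids, map, H)
}

read_hapmatrix <- function(path) {
  map_path <- paste0(path, ".map")
  if (!file.exists(map_path)) {
    stop("hapmatrix-tsv requires sidecar map file: ", map_path,
         call. = FALSE)
  }
  mp <- fread(map_path, sep = "\t", colClasses = list(character = "chrom"))
  need <- c("marker_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(mp))) {
    stop("parse error in ", map_path, ": needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  map <- marker_map(mp$marker_id, mp$chrom, mp$pos, mp$ref, mp$alt)
  m <- fread(path, sep = "\t", header = TRUE)
  rowids <- m[[1]]
  vals <- as.matrix(m[, -1, with = FALSE])
  if (!identical(colnames(vals), map$marker_id)) {
    stop("parse error in ", path, ": marker columns do not match map",
         call. = FALSE)
  }
  if (nrow(vals) %% 2L != 0L) {
    stop("parse error in ", path, ": expected two rows per individual",
         call. = FALSE)
  }
  a_rows <- seq(1L, nrow(vals), by = 2L)
  ids <- sub("_A$", "", rowids[a_rows])
  exp_rows <- paste0(rep(ids, each = 2L), c("_A", "_B"))
  if (!identical(rowids, exp_rows)) {
    bad <- which(rowids != exp_rows)[1]
    stop("parse error in ", path, " data row ", bad,
         ": row ids must alternate <id>_A, <id>_B", call. = FALSE)
  }
  phased_genotypes(ids, map, vals)
}

#' Write phased genotypes in the haplotype-matrix TSV dialect
#'
#' Writes the two-rows-per-individual TSV plus the `<path>.map` sidecar so
#' [read_phased_genotypes()] round-trips the object.
#'
#' @param pg a [phased_genotypes()] object
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_hapmatrix <- function(pg, path) {
  dt <- data.table(id = rownames(pg$H))
  dt <- cbind(dt, as.data.table(pg$H))
  fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  fwrite(pg$map[, .(marker_id, chrom, pos, ref, alt)],
         paste0(path, ".map"), sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write phased genotypes as a phased VCF
#'
#' Minimal VCF 4.2 writer (GT field only, `|` separators). Missing alleles
#' become `.`.
#'
#' @param pg a [phased_genotypes()] object
#' @param path output VCF path
#' @return `path`, invisibly
#' @export
write_phased_vcf <- function(pg, path) {
  n <- length(pg$ids)
  a <- pg$H[seq(1L, 2L * n, 2L), , drop = FALSE]
  b <- pg$H[seq(2L, 2L * n, 2L), , drop = FALSE]
  tochar <- function(x) ifelse(is.na(x), ".", as.character(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", pg$ids), collapse = "\t")), con)
  for (k in seq_len(nrow(pg$map))) {
    gt <- paste0(tochar(a[, k]), "|", tochar(b[, k]))
    writeLines(paste(c(pg$map$chrom[k], pg$map$pos[k], pg$map$marker_id[k],
                       pg$map$ref[k], pg$map$alt[k], ".", "PASS", ".", "GT",
                       gt), collapse = "\t"), con)
  }
  invisible(path)
}

# documented, stable column orders for result tables
.result_columns <- list(
  hhd = c("id", "chrom", "start", "end", "length_snp", "freq",
          "n_genotyped", "n_carriers", "obs_hom", "exp_random", "p_random",
          "n_carrier_matings", "exp_mating", "p_mating"),
  effects = c("haplotype_id", "term", "n", "estimate", "se", "z", "p"),
  gwas = c("marker", "chrom", "pos", "freq", "b", "se", "p"),
  traits = c("animal", "trait", "value", "parity")
)

#' Write a results table
#'
#' Writes TSV output with a documented, stable column order per result
#' kind; numeric columns are rounded to 10 significant digits so a write /
#' read cycle is lossless at that precision. Columns beyond the documented
#' set (covariates, diagnostics) are appended after it in input order.
#'
#' @param table a data.frame/data.table
#' @param path output path
#' @param kind one of `"hhd"`, `"effects"`, `"gwas"`, `"traits"`
#' @return `path`, invisibly
#' @export
write_results <- function(table, path, kind = c("hhd", "effects", "gwas",
                                                "traits")) {
  kind <- match.arg(kind)
  dt <- as.data.table(table)
  lead <- intersect(.result_columns[[kind]], names(dt))
  setcolorder(dt, c(lead, setdiff(names(dt), lead)))
  num <- names(dt)[vapply(dt, is.double, logical(1))]
  for (cn in num) set(dt, j = cn, value = signif(dt[[cn]], 10))
  ok <- tryCatch({
    fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("io error writing ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path TSV path
#' @param kind result kind (checked against the documented column order)
#' @return a `data.table`
#' @export
read_results <- function(path, kind = c("hhd", "effects", "gwas",
                                        "traits")) {
  kind <- match.arg(kind)
  dt <- fread(path, sep = "\t", na.strings = "NA")
  lead <- intersect(.result_columns[[kind]], names(dt))
  if (!length(lead) && nrow(dt)) {
    stop("parse error in ", path, ": not a '", kind, "' results table",
         call. = FALSE)
  }
  dt
}

#' Read calving records
#'
#' CSV with header `dam,sire,calf,date,parity,calf_sex,outcome,twin`
#' (optional extra columns such as `herd` are kept). Outcome categories
#' must be one of `stillborn`, `died_during_calving`, `died_within_24h`,
#' `abortion`, `live`.
#'
#' @param path CSV path
#' @return `data.table` of calving records
#' @export
read_calving_records <- function(path) {
  dt <- fread(path, colClasses = list(character = c("dam", "sire", "calf")))
  need <- c("dam", "sire", "calf", "date", "parity", "calf_sex", "outcome",
            "twin")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("parse error in ", path, ": missing columns ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(dt$outcome), calving_outcomes())
  if (length(bad)) stop("validation error: unknown outcome category: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  dt[, date := as.Date(date)]
  dt[]
}

#' Calving outcome categories
#' @return character vector of the recognised outcome codes
#' @export
calving_outcomes <- function() {
  c("stillborn", "died_during_calving", "died_within_24h", "abortion",
    "live")
}

#' Read insemination records
#'
#' CSV with header `cow,date,technician,lactation` (extra columns kept).
#' Lactation must be 0-3 (maiden heifers are lactation 0).
#'
#' @param path CSV path
#' @return `data.table` of insemination records
#' @export
read_insemination_records <- function(path) {
  dt <- fread(path, colClasses = list(character = "cow"))
  need <- c("cow", "date", "technician", "lactation")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("parse error in ", path, ": missing columns ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(dt$lactation %notin% 0:3)) {
    stop("validation error: lactation must be in 0..3", call. = FALSE)
  }
  dt[, date := as.Date(date)]
  dt[]
}

#' Read a YAML run configuration
#'
#' @param path YAML file
#' @return named list
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}
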