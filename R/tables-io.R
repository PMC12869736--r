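#' Classify salinity into wetland stress classes
#'
#' Freshwater: salinity <= 1 psu; brackish: 1 < salinity <= 35 psu; saline:
#' salinity > 35 psu (boundaries closed as in the standard wetland
#' classification).
#'
#' @param salinity numeric vector, psu; must be finite and positive.
#' @return factor with levels `freshwater < brackish < saline`.
#' @examples
#' classifyStress(c(0.2, 1, 35, 440))
#' @export
classifyStress <- function(salinity) {
  if (any(!is.finite(salinity)) || any(salinity <= 0))
    stop("salinity must be finite and positive (psu)", call. = FALSE)
  factor(ifelse(salinity <= 1, "freshwater",
                ifelse(salinity <= 35, "brackish", "saline")),
         levels = c("freshwater", "brackish", "saline"), ordered = TRUE)
}

#' Rarefy an ASV table to even depth
#'
#' Seeded subsampling without replacement (multivariate hypergeometric draw
#' per sample) to a common depth. Taxa whose columns become all-zero are
#' retained and flagged in the result's `rowData` (`allZero` column).
#'
#' @param x an [AsvExperiment-class].
#' @param depth target reads per sample; every sample must have at least
#'   this many reads.
#' @param seed RNG seed.
#' @return A rarefied [AsvExperiment-class] with every column sum equal to
#'   `depth`.
#' @export
rarefyTable <- function(x, depth, seed = 1L) {
  cts <- asvCounts(x)
  tot <- colSums(cts)
  shallow <- colnames(cts)[tot < depth]
  if (length(shallow))
    stop("samples shallower than depth ", depth, ": ",
         paste(shallow, collapse = ", "), call. = FALSE)
  set.seed(seed)
  out <- apply(cts, 2, function(col) {
    if (sum(col) == depth) return(col)
    drawn <- sample(rep.int(seq_along(col), col), depth)
    tabulate(drawn, nbins = length(col))
  })
  dimnames(out) <- dimnames(cts)
  res <- AsvExperiment(out, sampleData(x), domainTag(x))
  SummarizedExperiment::rowData(res)$allZero <- rowSums(out) == 0
  res
}

#' Hellinger transform
#'
#' Per-sample square-root of relative abundance: cell = sqrt(count / sample
#' total), so each sample's sum of squares is 1.
#'
#' @param x an [AsvExperiment-class] or a counts matrix (taxa x samples).
#' @return numeric matrix, same shape as the counts.
#' @export
hellingerTransform <- function(x) {
  cts <- if (is(x, "AsvExperiment")) asvCounts(x) else as.matrix(x)
  tot <- colSums(cts)
  if (any(tot == 0))
    stop("all-zero sample(s): ",
         paste(colnames(cts)[tot == 0], collapse = ", "), call. = FALSE)
  sqrt(sweep(cts, 2, tot, "/"))
}

#' Centered log-ratio transform
#'
#' cell = ln((count + pc) / geometric mean of the sample's (counts + pc));
#' each sample (column) sums to zero.
#'
#' @param x an [AsvExperiment-class] or counts matrix (taxa x samples).
#' @param pseudocount positive shift applied to every cell (default 1).
#' @return numeric matrix of CLR values.
#' @export
clrTransform <- function(x, pseudocount = 1) {
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be positive", call. = FALSE)
  cts <- if (is(x, "AsvExperiment")) asvCounts(x) else as.matrix(x)
  lg <- log(cts + pseudocount)
  sweep(lg, 2, colMeans(lg), "-")
}

#' Read / write ASV tables as TSV
#'
#' Tab-separated, UTF-8, `#` comment lines allowed; samples as rows and
#' taxa as columns (first column = sample id). `writeAsvTable()` /
#' `readAsvTable()` round-trip counts exactly.
#'
#' @param path file path.
#' @param domain domain tag for the returned object.
#' @param sampleData optional per-sample metadata data.frame.
#' @return `readAsvTable()`: an [AsvExperiment-class]; `writeAsvTable()`:
#'   the path, invisibly.
#' @export
readAsvTable <- function(path, domain = "bacteria", sampleData = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE, row.names = 1)
  AsvExperiment(as.matrix(df), sampleData, domain, samplesAsRows = TRUE)
}

#' @rdname readAsvTable
#' @param x an [AsvExperiment-class].
#' @export
writeAsvTable <- function(x, path) {
  m <- t(asvCounts(x))
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write BIOM v1 (JSON) tables
#'
#' Thin wrappers over the biomformat package; counts round-trip exactly.
#'
#' @param path file path.
#' @param domain domain tag for the returned object.
#' @return `readBiomTable()`: an [AsvExperiment-class]; `writeBiomTable()`:
#'   the path, invisibly.
#' @export
readBiomTable <- function(path, domain = "bacteria") {
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")  # taxa x samples
  AsvExperiment(m, NULL, domain)
}

#' @rdname readBiomTable
#' @param x an [AsvExperiment-class].
#' @export
writeBiomTable <- function(x, path) {
  b <- biomformat::make_biom(asvCounts(x))
  biomformat::write_biom(b, path)
  invisible(path)
}

#' Parse a QIIME2-style taxonomy TSV
#'
#' Two-column TSV (feature id, 7-rank semicolon-separated lineage with
#' optional `d__`/`p__`-style prefixes). Ranks are split into columns;
#' missing ranks are NA. The lineage is parsed, not validated against a
#' reference database.
#'
#' @param path file path.
#' @return data.frame: `taxon`, `domain_rank`, `phylum`, `class`, `order`,
#'   `family`, `genus`, `species`.
#' @export
readTaxonomy <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  ranks <- c("domain_rank", "phylum", "class", "order", "family",
             "genus", "species")
  parts <- strsplit(df[[2]], ";\\s*")
  out <- t(vapply(parts, function(p) {
    p <- sub("^[a-z]__", "", trimws(p))
    p[p == ""] <- NA_character_
    length(p) <- 7
    p
  }, character(7)))
  colnames(out) <- ranks
  cbind(data.frame(taxon = df[[1]], stringsAsFactors = FALSE),
        as.data.frame(out, stringsAsFactors = FALSE))
}
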