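#' Read a phased haplotype panel
#'
#' Reads a panel from either a phased VCF (GT fields with `|`) or the
#' package's haplotype-TSV dialect: one row per marker, the four marker-map
#' columns first, then one 0/1 column per haplotype named `<id>.1`/`<id>.2`.
#' Breed and sex labels travel in a sidecar table
#' (`<path>.samples.tsv`, columns `individual_id`, `breed`, `sex`) because
#' VCF has no standard slot for them; if the sidecar is absent, breed
#' defaults to `"unknown"` and sex alternates M/F.
#'
#' @param path file to read.
#' @param format `"vcf"` or `"tsv"`; guessed from the file extension when
#'   missing.
#' @return A [haplotype_panel()].
#' @export
read_panel <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") panel <- read_panel_vcf(path)
  else panel <- read_panel_tsv(path)
  side <- sidecar_path(path)
  if (file.exists(side)) {
    meta <- read.table(side, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE, colClasses = "character")
    idx <- match(panel$individual_id, meta$individual_id)
    if (anyNA(idx))
      stop("sidecar ", side, " is missing individuals: ",
           paste(panel$individual_id[is.na(idx)], collapse = ", "))
    panel$breed <- meta$breed[idx]
    panel$sex <- meta$sex[idx]
  }
  panel
}

sidecar_path <- function(path) paste0(path, ".samples.tsv")

read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- grepl(",", alt) | nchar(alt) != 1 | nchar(ref) != 1
  if (any(multi))
    stop("non-biallelic SNP site(s): ",
         paste(fix[multi, "ID"], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  samples <- colnames(v@gt)[-1]
  bad <- which(is.na(gt) | !grepl("^[01]\\|[01]$", gt), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("unphased or missing genotype at marker ",
         fix[bad[1, 1], "ID"], " sample ", samples[bad[1, 2]])
  ids <- fix[, "ID"]
  if (anyNA(ids) || any(ids == "."))
    ids <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  map <- marker_map(ids, fix[, "CHROM"], as.numeric(fix[, "POS"]))
  h1 <- substr(gt, 1, 1)
  h2 <- substr(gt, 3, 3)
  alleles <- matrix(0L, nrow(map), 2 * length(samples))
  alleles[, seq(1, ncol(alleles), by = 2)] <- as.integer(h1)
  alleles[, seq(2, ncol(alleles), by = 2)] <- as.integer(h2)
  n <- length(samples)
  haplotype_panel(map, alleles, samples, rep("unknown", n),
                  rep(c("M", "F"), length.out = n))
}

read_panel_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c("marker_id", "chromosome", "position_bp", "position_cM")
  if (!all(need %in% names(tab)[1:4]))
    stop("haplotype-TSV must start with columns ",
         paste(need, collapse = ", "))
  map <- marker_map(tab$marker_id, tab$chromosome, tab$position_bp,
                    tab$position_cM)
  hcols <- setdiff(names(tab), need)
  alleles <- as.matrix(tab[, hcols, drop = FALSE])
  if (length(alleles) > 0 && !all(alleles %in% 0:1))
    stop("haplotype-TSV body must be 0/1")
  base <- sub("\\.[12]$", "", hcols)
  ids <- unique(base)
  want <- if (length(ids) > 0)
    paste0(rep(ids, each = 2), c(".1", ".2")) else character(0)
  if (!identical(hcols, want))
    stop("haplotype columns must come in <id>.1, <id>.2 pairs")
  n <- length(ids)
  haplotype_panel(map, alleles, ids, rep("unknown", n),
                  rep(c("M", "F"), length.out = n))
}

#' Write a phased haplotype panel
#'
#' Writes the formats read by [read_panel()], plus the breed/sex sidecar
#' table at `<path>.samples.tsv`. The round trip
#' `read_panel(write_panel(p))` reproduces the panel exactly.
#'
#' @param panel a [haplotype_panel()].
#' @param path output file.
#' @param format `"vcf"` or `"tsv"`; guessed from the extension when
#'   missing.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf$", path)) "vcf" else "tsv"
  if (format == "vcf") write_panel_vcf(panel, path)
  else write_panel_tsv(panel, path)
  meta <- data.frame(individual_id = panel$individual_id,
                     breed = panel$breed, sex = panel$sex,
                     stringsAsFactors = FALSE)
  write.table(meta, sidecar_path(path), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

write_panel_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=nativesel",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", panel$individual_id), collapse = "\t")
  writeLines(header, con)
  n <- n_individuals(panel)
  if (n > 0 && nrow(panel$map) > 0) {
    h1 <- panel$alleles[, seq(1, 2 * n, by = 2), drop = FALSE]
    h2 <- panel$alleles[, seq(2, 2 * n, by = 2), drop = FALSE]
    gt <- matrix(paste0(h1, "|", h2), nrow = nrow(panel$map))
    body <- cbind(panel$map$chromosome,
                  format(panel$map$position_bp, scientific = FALSE,
                         trim = TRUE),
                  panel$map$marker_id, "A", "B", ".", "PASS", ".", "GT", gt)
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

write_panel_tsv <- function(panel, path) {
  tab <- cbind(panel$map[, c("marker_id", "chromosome", "position_bp",
                             "position_cM")],
               as.data.frame(panel$alleles, check.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a marker map as TSV
#'
#' @param path file path.
#' @return `read_marker_map` returns a `marker_map`; `write_marker_map`
#'   returns `path` invisibly.
#' @export
read_marker_map <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  marker_map(tab$marker_id, tab$chromosome, tab$position_bp,
             if ("position_cM" %in% names(tab)) tab$position_cM
             else tab$position_bp / 1e6)
}

#' @rdname read_marker_map
#' @param map a `marker_map`.
#' @export
write_marker_map <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write a symmetric matrix with ids
#'
#' TSV with the ids as header row and first column. The round trip is
#' lossless to at least 12 significant digits.
#'
#' @param m symmetric numeric matrix with row/column names.
#' @param path file path.
#' @return `read_matrix` returns the matrix; `write_matrix` returns `path`
#'   invisibly.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (!isSymmetric(unname(m), tol = 1e-12)) stop("matrix must be symmetric")
  if (is.null(rownames(m)))
    rownames(m) <- colnames(m) <- paste0("id", seq_len(nrow(m)))
  tab <- cbind(id = rownames(m),
               as.data.frame(format(m, digits = 15, trim = TRUE,
                                    scientific = TRUE),
                             check.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  ids <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

#' Write a per-generation metrics table as CSV
#'
#' @param metrics a data.frame of per-generation summaries.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
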