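#' Build a marker map
#'
#' A marker map holds the genomic coordinates used for segment lengths and
#' recombination. Positions must be strictly increasing within a chromosome
#' and marker ids unique. If no genetic positions are supplied they are
#' derived from physical positions by the 1 cM = 1 Mb convention.
#'
#' @param marker_id character vector of unique marker names.
#' @param chromosome chromosome label per marker (markers of a chromosome
#'   must be contiguous and in map order).
#' @param position_bp 1-based physical position in base pairs.
#' @param position_cM genetic position in centimorgan; defaults to
#'   `position_bp / 1e6`.
#' @return A `data.frame` of class `marker_map` with columns `marker_id`,
#'   `chromosome`, `position_bp`, `position_cM`.
#' @examples
#' make_marker_map(n_chr = 2, markers_per_chr = 5, spacing_bp = 1e6)
#' @export
marker_map <- function(marker_id, chromosome, position_bp,
                       position_cM = position_bp / 1e6) {
  stopifnot(length(marker_id) == length(chromosome),
            length(marker_id) == length(position_bp))
  if (anyDuplicated(marker_id) > 0)
    stop("marker ids must be unique")
  if (any(position_bp < 0) || any(position_cM < 0))
    stop("positions must be non-negative")
  map <- data.frame(marker_id = as.character(marker_id),
                    chromosome = as.character(chromosome),
                    position_bp = as.numeric(position_bp),
                    position_cM = as.numeric(position_cM),
                    stringsAsFactors = FALSE)
  for (chr in unique(map$chromosome)) {
    p <- map$position_bp[map$chromosome == chr]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", chr)
  }
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Generate a regular marker map
#'
#' Convenience constructor for simulation studies: `n_chr` chromosomes with
#' `markers_per_chr` equally spaced markers each.
#'
#' @param n_chr number of chromosomes.
#' @param markers_per_chr markers per chromosome.
#' @param spacing_bp distance between adjacent markers in bp (default 1e5,
#'   i.e. 50K-chip-like density).
#' @param start_bp position of the first marker on each chromosome.
#' @return A `marker_map`.
#' @export
make_marker_map <- function(n_chr = 3, markers_per_chr = 500,
                            spacing_bp = 1e5, start_bp = spacing_bp) {
  chr <- rep(paste0("chr", seq_len(n_chr)), each = markers_per_chr)
  pos <- rep(start_bp + spacing_bp * (seq_len(markers_per_chr) - 1), n_chr)
  id <- paste0(chr, "_m", rep(seq_len(markers_per_chr), n_chr))
  marker_map(id, chr, pos)
}

#' Per-marker genome weights
#'
#' Weights used to turn per-marker indicators into genome proportions.
#' With `method = "length"` each marker represents the physical interval
#' reaching halfway to each neighbour, clipped at the terminal markers of
#' the chromosome; with `method = "count"` all markers weigh equally.
#' Weights are normalized to sum to 1 over the genome.
#'
#' @param map a `marker_map`.
#' @param method `"length"` (default) or `"count"`.
#' @return numeric vector of weights summing to 1.
#' @export
marker_weights <- function(map, method = c("length", "count")) {
  method <- match.arg(method)
  m <- nrow(map)
  if (method == "count") return(rep(1 / m, m))
  w <- numeric(m)
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    p <- map$position_bp[idx]
    k <- length(idx)
    if (k == 1) { w[idx] <- 0; next }
    half <- diff(p) / 2
    w[idx] <- c(half[1], if (k > 2) half[-1] + half[-(k - 1)] else NULL,
                half[k - 1])
  }
  if (sum(w) == 0) stop("degenerate map: zero total length")
  w / sum(w)
}

# 0-based inclusive chromosome block indices for the C++ kernels
chrom_blocks <- function(map) {
  r <- rle(map$chromosome)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  list(start = as.integer(starts - 1), end = as.integer(ends - 1),
       chromosome = r$values)
}

#' Construct a phased haplotype panel
#'
#' The central data container: a phased biallelic allele matrix with one row
#' per marker and two columns per individual (maternal and paternal
#' haplotype, named `<id>.1` and `<id>.2`), plus a marker map and per-
#' individual breed and sex labels.
#'
#' @param map a `marker_map`.
#' @param alleles integer matrix of 0/1 alleles, `nrow(map)` rows and
#'   `2 * length(individual_id)` columns in individual order.
#' @param individual_id unique individual names.
#' @param breed breed label per individual.
#' @param sex `"M"` or `"F"` per individual.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(map, alleles, individual_id, breed, sex) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n <- length(individual_id)
  if (nrow(alleles) != nrow(map))
    stop("allele matrix has ", nrow(alleles), " rows but map has ",
         nrow(map), " markers")
  if (ncol(alleles) != 2 * n)
    stop("allele matrix must have two columns per individual")
  if (n > 0 && anyDuplicated(individual_id) > 0)
    stop("individual ids must be unique")
  if (length(breed) != n || length(sex) != n)
    stop("breed and sex must have one entry per individual")
  if (n > 0 && !all(sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'")
  if (length(alleles) > 0 && !all(alleles %in% 0:1))
    stop("alleles must be 0 or 1 (phased, no missing values)")
  colnames(alleles) <- if (n > 0)
    paste0(rep(individual_id, each = 2), c(".1", ".2")) else character(0)
  structure(list(map = map, alleles = alleles,
                 individual_id = as.character(individual_id),
                 breed = as.character(breed), sex = as.character(sex)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", length(x$individual_id), "individuals,",
      nrow(x$map), "markers,",
      length(unique(x$map$chromosome)), "chromosomes\n")
  tb <- table(x$breed)
  cat("breeds:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of individuals in a panel
#' @param panel a `haplotype_panel`.
#' @return integer count.
#' @export
n_individuals <- function(panel) length(panel$individual_id)

#' Haplotype column indices of given individuals
#' @param i integer vector of individual indices.
#' @return integer vector of the corresponding allele-matrix columns.
#' @export
hap_cols <- function(i) as.vector(rbind(2L * i - 1L, 2L * i))

#' Subset a panel by individuals
#' @param panel a `haplotype_panel`.
#' @param i integer or logical index over individuals, or a breed name
#'   via `breed =`.
#' @param breed optional breed label; selects all its individuals.
#' @return A `haplotype_panel` with the selected individuals.
#' @export
panel_subset <- function(panel, i = NULL, breed = NULL) {
  if (is.null(i)) {
    if (is.null(breed)) stop("give either i or breed")
    i <- which(panel$breed %in% breed)
  }
  if (is.logical(i)) i <- which(i)
  haplotype_panel(panel$map, panel$alleles[, hap_cols(i), drop = FALSE],
                  panel$individual_id[i], panel$breed[i], panel$sex[i])
}

#' Combine panels sharing a marker map
#' @param ... `haplotype_panel` objects with identical maps.
#' @return A combined `haplotype_panel`.
#' @export
panel_bind <- function(...) {
  ps <- list(...)
  map <- ps[[1]]$map
  for (p in ps[-1])
    if (!identical(p$map$marker_id, map$marker_id))
      stop("panels must share the same marker map")
  haplotype_panel(map, do.call(cbind, lapply(ps, `[[`, "alleles")),
                  unlist(lapply(ps, `[[`, "individual_id")),
                  unlist(lapply(ps, `[[`, "breed")),
                  unlist(lapply(ps, `[[`, "sex")))
}

#' Allele dosage matrix
#'
#' @param panel a `haplotype_panel`.
#' @return integer matrix (markers x individuals) of 0/1/2 counts of the
#'   alternative allele.
#' @export
dosage <- function(panel) {
  n <- n_individuals(panel)
  if (n == 0) return(matrix(integer(0), nrow(panel$map), 0))
  d <- panel$alleles[, seq(1, 2 * n, by = 2), drop = FALSE] +
    panel$alleles[, seq(2, 2 * n, by = 2), drop = FALSE]
  colnames(d) <- panel$individual_id
  d
}

#' Allele frequencies of a panel
#' @param panel a `haplotype_panel`.
#' @return numeric vector of per-marker frequencies of the 1 allele.
#' @export
allele_freq <- function(panel) rowMeans(panel$alleles)

#' Observed heterozygosity
#'
#' Mean over individuals and markers of the heterozygosity indicator
#' (the two haplotypes of an individual carry different alleles).
#'
#' @param panel a `haplotype_panel`.
#' @return scalar in \[0, 1\].
#' @export
observed_heterozygosity <- function(panel) {
  n <- n_individuals(panel)
  if (n == 0) stop("empty panel")
  het <- panel$alleles[, seq(1, 2 * n, by = 2), drop = FALSE] !=
    panel$alleles[, seq(2, 2 * n, by = 2), drop = FALSE]
  mean(het)
}
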