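#' Construct an autosomal genetic map
#'
#' A genetic map is the ordered set of autosomes on which ENU alleles are
#' placed, each with a length in centimorgans (cM). Sex chromosomes are
#' deliberately excluded: the screened gene universe is autosomal and the
#' breeding design (G2 daughters backcrossed to the G1 sire) is modeled
#' without X-linked inheritance.
#'
#' @param chrom Character vector of unique chromosome labels.
#' @param length_cM Numeric vector of strictly positive map lengths, in cM.
#' @return A `genetic_map`: a data frame with columns `chrom` and
#'   `length_cM`, rows in map order.
#' @examples
#' genetic_map(c("chr1", "chr2"), c(98, 104))
#' @export
genetic_map <- function(chrom, length_cM) {
  chrom <- as.character(chrom)
  length_cM <- as.numeric(length_cM)
  if (length(chrom) != length(length_cM) || length(chrom) == 0L) {
    stop("`chrom` and `length_cM` must be non-empty vectors of equal length")
  }
  if (anyDuplicated(chrom)) {
    stop("chromosome ids must be unique")
  }
  if (any(!is.finite(length_cM)) || any(length_cM <= 0)) {
    stop("all chromosome lengths must be finite and strictly positive (cM)")
  }
  structure(
    data.frame(chrom = chrom, length_cM = length_cM, stringsAsFactors = FALSE),
    class = c("genetic_map", "data.frame")
  )
}

#' Default mouse autosome map
#'
#' Nineteen autosomes with plausible mouse map lengths in cM, shipped as a
#' modeling default in `inst/extdata/mouse_autosome_map.tsv`. The values are
#' round figures of the right magnitude for the mouse genetic map (total
#' about 1440 cM); they are a simulation default, not measured data.
#'
#' @return A [genetic_map()].
#' @export
default_mouse_map <- function() {
  path <- system.file("extdata", "mouse_autosome_map.tsv",
                      package = "enuscreen", mustWork = TRUE)
  read_genetic_map(path)
}

#' Read / write a genetic map as TSV
#'
#' The interchange format is a two-column TSV with header
#' `chrom<TAB>length_cM`.
#'
#' @param path File path.
#' @return `read_genetic_map()` returns a [genetic_map()];
#'   `write_genetic_map()` returns `path` invisibly.
#' @export
read_genetic_map <- function(path) {
  tab <- read_clean_tsv(path, required = c("chrom", "length_cM"))
  genetic_map(tab$chrom, as.numeric(tab$length_cM))
}

#' @rdname read_genetic_map
#' @param map A [genetic_map()].
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  utils::write.table(as.data.frame(map), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Haldane map function
#'
#' Converts genetic distance to recombination fraction assuming crossovers
#' form a Poisson process with no interference:
#' r = (1 - exp(-2 d / 100)) / 2 for d in centimorgans. This is the map
#' function consistent with the Poisson crossover model used by
#' [simulate_gamete()], so simulated recombinant fractions converge to it.
#'
#' @param distance_cM Numeric vector of non-negative, finite distances (cM).
#' @return Recombination fractions in `[0, 0.5)`.
#' @examples
#' haldane_rf(c(0, 1, 50, 1000))
#' @export
haldane_rf <- function(distance_cM) {
  if (!is.numeric(distance_cM) || any(!is.finite(distance_cM)) ||
      any(distance_cM < 0)) {
    stop("`distance_cM` must be finite and non-negative")
  }
  0.5 * (1 - exp(-2 * distance_cM / 100))
}

# Validate that loci (data frame with chrom, pos_cM) lie on the map.
# Returns the map row index for each locus.
match_loci_to_map <- function(loci, map) {
  idx <- match(loci$chrom, map$chrom)
  if (anyNA(idx)) {
    bad <- unique(loci$chrom[is.na(idx)])
    stop("loci on chromosomes absent from the map: ", paste(bad, collapse = ", "))
  }
  pos <- as.numeric(loci$pos_cM)
  if (any(!is.finite(pos)) || any(pos < 0) || any(pos > map$length_cM[idx])) {
    stop("locus positions must lie within [0, chromosome length] cM")
  }
  idx
}

#' Simulate one gamete from a multiply heterozygous parent
#'
#' Models a single meiosis over the parent's heterozygous loci. All mutant
#' alleles are assumed to be in cis (they arrived on one parental gamete,
#' as ENU alleles do in a G1 sire or a G2 daughter), so a gamete is fully
#' described by which strand it carries at each locus. Per chromosome the
#' crossover count is Poisson with mean `length_cM / 100`, crossover
#' positions are uniform, the starting strand is a fair coin, and the strand
#' flips at each crossover; chromosomes assort independently.
#'
#' Consumes the current R random stream; seed it with [set.seed()] (or use
#' the seeded top-level drivers) for reproducibility.
#'
#' @param loci Data frame with columns `chrom` and `pos_cM`: the parent's
#'   heterozygous loci.
#' @param map A [genetic_map()] covering every locus.
#' @return Logical vector, one element per locus: `TRUE` where the gamete
#'   carries the mutant strand.
#' @export
simulate_gamete <- function(loci, map) {
  stopifnot(inherits(map, "genetic_map"))
  n <- nrow(loci)
  out <- logical(n)
  if (n == 0L) return(out)
  map_idx <- match_loci_to_map(loci, map)
  for (ci in unique(map_idx)) {
    at <- which(map_idx == ci)
    len <- map$length_cM[ci]
    mutant_first <- stats::runif(1) < 0.5
    n_cx <- stats::rpois(1, len / 100)
    if (n_cx > 0L) {
      cx <- sort(stats::runif(n_cx, 0, len))
      flips <- findInterval(loci$pos_cM[at], cx) %% 2L == 1L
    } else {
      flips <- rep(FALSE, length(at))
    }
    out[at] <- xor(mutant_first, flips)
  }
  out
}
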