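#' Piecewise-constant recombination landscape
#'
#' Describes the crossover intensity along one chromosome as a piecewise
#' constant function, together with the total genetic length of the
#' chromosome. A `zero_zone` (typically the centromeric satellite array)
#' forces the intensity to exactly zero over an interval, so that no
#' simulated crossover can ever fall inside it.
#'
#' All coordinates are 0-based, half-open.
#'
#' @param chrom_length Chromosome length in bp.
#' @param breakpoints Internal segment breakpoints (bp), strictly increasing,
#'   all in `(0, chrom_length)`. `NULL` for a single uniform segment.
#' @param rates Relative (non-negative) intensity per segment; length must be
#'   `length(breakpoints) + 1`. Only ratios matter: the landscape is
#'   normalised so that it integrates to `total_cm`.
#' @param total_cm Total genetic length of the chromosome in centiMorgans.
#'   The expected number of crossovers per gamete is `total_cm / 100`.
#' @param zero_zone Optional `c(start, end)` interval (bp) whose intensity is
#'   forced to zero, e.g. the satellite array span.
#' @param chrom Chromosome name.
#'
#' @return An object of class `"recombination_landscape"`: a list with the
#'   segment table (`segments`: start, end, rate), `chrom_length`,
#'   `total_cm`, `zero_zone` and `chrom`.
#' @examples
#' land <- recombination_landscape(1e7, total_cm = 50,
#'                                 zero_zone = c(4e6, 6e6))
#' land
#' @export
recombination_landscape <- function(chrom_length, breakpoints = NULL,
                                    rates = NULL, total_cm,
                                    zero_zone = NULL, chrom = "chr1") {
  if (!is.numeric(chrom_length) || length(chrom_length) != 1 ||
      chrom_length <= 0) {
    stop("'chrom_length' must be a single positive number")
  }
  if (total_cm < 0) stop("'total_cm' must be non-negative")
  if (is.null(breakpoints)) breakpoints <- numeric(0)
  if (is.null(rates)) rates <- rep(1, length(breakpoints) + 1L)
  if (length(rates) != length(breakpoints) + 1L) {
    stop("'rates' must have one more element than 'breakpoints'")
  }
  if (any(rates < 0)) stop("all rates must be non-negative")
  if (is.unsorted(breakpoints, strictly = TRUE) ||
      any(breakpoints <= 0) || any(breakpoints >= chrom_length)) {
    stop("'breakpoints' must be strictly increasing within (0, chrom_length)")
  }
  bounds <- c(0, breakpoints, chrom_length)
  seg <- data.frame(start = bounds[-length(bounds)], end = bounds[-1],
                    rate = as.numeric(rates))
  if (!is.null(zero_zone)) {
    stopifnot(length(zero_zone) == 2, zero_zone[1] < zero_zone[2],
              zero_zone[1] >= 0, zero_zone[2] <= chrom_length)
    seg <- .split_segments(seg, zero_zone)
    in_zone <- seg$start >= zero_zone[1] & seg$end <= zero_zone[2]
    seg$rate[in_zone] <- 0
  }
  mass <- sum(seg$rate * (seg$end - seg$start))
  if (total_cm > 0 && mass <= 0) {
    stop("landscape intensity integrates to zero but 'total_cm' > 0")
  }
  structure(list(segments = seg, chrom_length = chrom_length,
                 total_cm = total_cm, zero_zone = zero_zone, chrom = chrom),
            class = "recombination_landscape")
}

# split piecewise segments at the two zone bounds
.split_segments <- function(seg, at) {
  for (x in at) {
    hit <- which(seg$start < x & seg$end > x)
    if (length(hit)) {
      s <- seg[hit, ]
      seg <- rbind(seg[-hit, ],
                   data.frame(start = s$start, end = x, rate = s$rate),
                   data.frame(start = x, end = s$end, rate = s$rate))
    }
  }
  seg[order(seg$start), , drop = FALSE]
}

#' @export
print.recombination_landscape <- function(x, ...) {
  cat(sprintf("Recombination landscape on %s: %.2f Mb, %.2f cM, %d segment(s)\n",
              x$chrom, x$chrom_length / 1e6, x$total_cm, nrow(x$segments)))
  if (!is.null(x$zero_zone)) {
    cat(sprintf("  zero-recombination zone: [%.2f, %.2f) Mb\n",
                x$zero_zone[1] / 1e6, x$zero_zone[2] / 1e6))
  }
  invisible(x)
}

#' Expected genetic length between two physical positions
#'
#' Integrates the normalised landscape intensity over `[from, to)` and
#' returns the result in centiMorgans.
#'
#' @param landscape A [recombination_landscape()].
#' @param from,to Physical bounds in bp.
#' @return Genetic length in cM.
#' @export
landscape_cm_between <- function(landscape, from, to) {
  seg <- landscape$segments
  mass <- sum(seg$rate * (seg$end - seg$start))
  if (mass == 0) return(0)
  ov <- pmax(0, pmin(seg$end, to) - pmax(seg$start, from))
  landscape$total_cm * sum(seg$rate * ov) / mass
}

#' Draw crossover positions from a landscape
#'
#' Samples `n` positions by inverse-CDF sampling of the normalised
#' piecewise-constant intensity. Positions never fall in zero-rate
#' segments.
#'
#' @param landscape A [recombination_landscape()].
#' @param n Number of positions to draw.
#' @return Numeric vector of `n` positions in bp.
#' @export
sample_crossover_positions <- function(landscape, n) {
  if (n == 0) return(numeric(0))
  mass <- .landscape_mass(landscape)
  if (mass <= 0) stop("cannot sample positions from a zero-intensity landscape")
  .positions_at_mass(landscape, stats::runif(n) * mass)
}

.landscape_mass <- function(landscape) {
  seg <- landscape$segments
  sum(seg$rate * (seg$end - seg$start))
}

# physical positions at given cumulative-intensity coordinates
.positions_at_mass <- function(landscape, u) {
  seg <- landscape$segments
  cum <- cumsum(seg$rate * (seg$end - seg$start))
  i <- findInterval(u, cum, left.open = TRUE) + 1L
  i <- pmin(i, nrow(seg))
  lo <- c(0, cum)[i]
  seg$start[i] + (u - lo) / seg$rate[i]
}

# crossover positions for one gamete: Poisson placement along the genetic
# map, or a thinned gamma renewal process when interference is requested
# (chiasma-scale inter-arrival ~ Gamma(nu, 2 nu) Morgans, each chiasma
# resolved to the sampled chromatid with probability 1/2)
.gamete_crossovers <- function(landscape, nu = NULL) {
  if (landscape$total_cm == 0) return(numeric(0))
  G <- landscape$total_cm / 100     # gamete map length in Morgans
  if (is.null(nu) || nu <= 1) {
    n_co <- stats::rpois(1, G)
    return(sort(sample_crossover_positions(landscape, n_co)))
  }
  # chiasma process at intensity 2 per Morgan of gamete map, gamma
  # inter-arrivals; burn-in from -3 Morgans for an approximately
  # stationary start
  y <- -3
  events <- numeric(0)
  while (y < G) {
    y <- y + stats::rgamma(1, shape = nu, rate = 2 * nu)
    if (y >= 0 && y < G) events <- c(events, y)
  }
  events <- events[stats::runif(length(events)) < 0.5]
  if (length(events) == 0) return(numeric(0))
  g <- events                       # genetic positions on the gamete map
  mass <- .landscape_mass(landscape)
  sort(.positions_at_mass(landscape, g / G * mass))
}
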