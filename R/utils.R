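#' @keywords internal
"_PACKAGE"

#' @importFrom stats dist quantile rnorm runif rbinom rpois cor uniroot
#'   optimize rlnorm setNames
#' @importFrom utils head
NULL

# Derive a reproducible sub-seed from a master seed and a stream name, so
# each generator sub-process draws from its own stream and adding a new
# generator never perturbs an existing one.  Kept below 2^31 - 1.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647L)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  force(expr)
}

# Minimum Euclidean distance from points (px, py) to the segment
# (x1,y1)-(x2,y2).  Vectorised over points.
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 < .Machine$double.eps) {
    return(sqrt((px - x1)^2 + (py - y1)^2))
  }
  t <- ((px - x1) * dx + (py - y1) * dy) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# Minimum distance from each point to a polyline given as a 2-column matrix
# of vertices.
point_polyline_distance <- function(px, py, vertices) {
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 2)
  d <- rep(Inf, length(px))
  for (k in seq_len(nrow(vertices) - 1)) {
    d <- pmin(d, point_segment_distance(
      px, py,
      vertices[k, 1], vertices[k, 2],
      vertices[k + 1, 1], vertices[k + 1, 2]
    ))
  }
  d
}

#' Format a count as a percentage of a total
#'
#' Reported percentages follow the truncation convention used in the
#' results this package mirrors: the ratio is multiplied by 100 and cut
#' (not rounded) at `digits` decimals. Half-to-even rounding is available
#' via `method = "round"`.
#'
#' @param count Numerator count.
#' @param total Denominator count.
#' @param digits Number of decimals retained (default 2).
#' @param method `"truncate"` (default) cuts at `digits`; `"round"` applies
#'   `round()` (half-to-even).
#' @return Numeric percentage on the 0-100 scale.
#' @examples
#' pct_of(125, 18411)        # 0.67
#' pct_of(119, 240, 1, "round")  # 49.6
#' @export
pct_of <- function(count, total, digits = 2,
                   method = c("truncate", "round")) {
  method <- match.arg(method)
  stopifnot(total > 0, count >= 0)
  p <- 100 * count / total
  if (method == "truncate") {
    trunc(p * 10^digits) / 10^digits
  } else {
    round(p, digits)
  }
}
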