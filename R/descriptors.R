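#' Geometric descriptors of one secondary structure element
#'
#' An SSE is summarised by the unweighted mean of its C-alpha coordinates
#' (its geometric centre of mass), the unit vector from its first to its
#' last C-alpha (the axis through the terminal C-alpha atoms), its summed
#' solvent accessibility, its residue count and a binary type flag
#' (0 for an alpha-helix, 1 otherwise).
#'
#' @param coords Numeric matrix (n x 3) of C-alpha coordinates, N-to-C.
#' @param kind `"helix"` or `"strand"`.
#' @param accessibility Per-residue solvent accessibility, Angstrom squared
#'   (length n). Default all zero.
#' @param acc_agg Aggregate for accessibility: `"sum"` (default, preserves
#'   the length signal) or `"mean"`.
#'
#' @return An object of class `sse_descriptor`: a list with `centroid`
#'   (3-vector), `axis` (unit 3-vector), `accessibility`, `length`, `sstype`.
#' @export
sse_geometry <- function(coords, kind, accessibility = rep(0, nrow(coords)),
                         acc_agg = c("sum", "mean")) {
  acc_agg <- match.arg(acc_agg)
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, all(is.finite(coords)))
  if (nrow(coords) < 3L) stop("an SSE needs at least 3 residues", call. = FALSE)
  v <- coords[nrow(coords), ] - coords[1, ]
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("degenerate axis: first and last C-alpha coincide", call. = FALSE)
  structure(
    list(
      centroid = colMeans(coords),
      axis = v / nv,
      accessibility = if (acc_agg == "sum") sum(accessibility) else mean(accessibility),
      length = nrow(coords),
      sstype = if (identical(kind, "helix")) 0 else 1
    ),
    class = "sse_descriptor"
  )
}

as_vec3 <- function(x, field) {
  if (inherits(x, "sse_descriptor")) x <- x[[field]]
  stopifnot(is.numeric(x), length(x) == 3L)
  x
}

#' Distance between two SSE centroids
#'
#' Euclidean distance, in Angstrom, between the geometric centres of mass of
#' two elements.
#'
#' @param a,b `sse_descriptor` objects (or bare centroid 3-vectors).
#' @return Non-negative scalar, Angstrom.
#' @export
pair_distance <- function(a, b) {
  sqrt(sum((as_vec3(a, "centroid") - as_vec3(b, "centroid"))^2))
}

#' Angle between two SSE axes
#'
#' Arc-cosine of the (clamped) dot product of the two unit axis vectors,
#' reported in degrees in \[0, 180\]. The N-to-C direction of each axis is
#' kept, so antiparallel elements score near 180.
#'
#' @param a,b `sse_descriptor` objects (or bare unit axis 3-vectors).
#' @return Angle in degrees.
#' @export
pair_angle <- function(a, b) {
  u <- as_vec3(a, "axis"); v <- as_vec3(b, "axis")
  d <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(max(-1, min(1, d))) * 180 / pi
}

#' Global sequence identity of two domain sequences
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap opening 10, gap
#' extension 0.5); identity is the number of identical aligned positions
#' divided by the aligned length including internal gap positions (the
#' classic PID1 denominator).
#'
#' @param seq_a,seq_b Amino-acid strings (one-letter codes).
#' @return Identity fraction in \[0, 1\].
#' @export
sequence_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b,
    type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Descriptor set of a whole domain
#'
#' Computes per-SSE descriptors ([sse_geometry()]) and the pairwise centroid
#' distances and inter-axis angles for all SSE pairs i < j.
#'
#' @param domain An `annotated_domain` (see [make_domain()]), or any list
#'   with a `residues` tibble (`x`,`y`,`z`,`acc`) and an `sses` tibble
#'   (`kind`,`start`,`end`).
#' @param acc_agg Passed to [sse_geometry()].
#'
#' @return An object of class `domain_descriptors`: list with `n` (SSE
#'   count), `per_sse` (tibble: `sse`, `accessibility`, `length`, `sstype`,
#'   centroid and axis components) and `pairs` (tibble: `i`, `j`,
#'   `distance`, `angle`).
#' @export
domain_descriptors <- function(domain, acc_agg = "sum") {
  res <- domain$residues
  sses <- domain$sses
  n <- nrow(sses)
  if (n < 2L) stop("a domain needs at least 2 SSEs", call. = FALSE)
  desc <- lapply(seq_len(n), function(k) {
    idx <- sses$start[k]:sses$end[k]
    sse_geometry(cbind(res$x[idx], res$y[idx], res$z[idx]),
                 kind = sses$kind[k],
                 accessibility = res$acc[idx],
                 acc_agg = acc_agg)
  })
  per_sse <- tibble(
    sse = seq_len(n),
    accessibility = vapply(desc, `[[`, 0, "accessibility"),
    length = vapply(desc, function(d) as.numeric(d$length), 0),
    sstype = vapply(desc, `[[`, 0, "sstype"),
    cx = vapply(desc, function(d) d$centroid[1], 0),
    cy = vapply(desc, function(d) d$centroid[2], 0),
    cz = vapply(desc, function(d) d$centroid[3], 0),
    ax = vapply(desc, function(d) d$axis[1], 0),
    ay = vapply(desc, function(d) d$axis[2], 0),
    az = vapply(desc, function(d) d$axis[3], 0)
  )
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  pairs <- tibble(
    i = ij[, 1], j = ij[, 2],
    distance = vapply(seq_len(nrow(ij)),
                      function(k) pair_distance(desc[[ij[k, 1]]], desc[[ij[k, 2]]]), 0),
    angle = vapply(seq_len(nrow(ij)),
                   function(k) pair_angle(desc[[ij[k, 1]]], desc[[ij[k, 2]]]), 0)
  )
  structure(list(n = n, per_sse = per_sse, pairs = pairs),
            class = "domain_descriptors")
}

#' Number of features describing a domain pair
#'
#' For two domains of N SSEs each, the feature vector holds, per SSE pair
#' i < j, the centroid distance and inter-axis angle of both domains
#' (2 x 2 x N(N-1)/2 values); per SSE, the accessibility, length and type of
#' both domains (2 x 3 x N values); four root-mean-square difference
#' features (distance, angle, accessibility, length); and the sequence
#' identity. Hence M = 2N(N-1) + 6N + 5.
#'
#' @param n_sses SSE count N (>= 2).
#' @return Integer M.
#' @export
feature_count <- function(n_sses) {
  if (any(n_sses < 2L)) stop("a domain pair needs N >= 2 SSEs", call. = FALSE)
  as.integer(2 * n_sses * (n_sses - 1) + 6 * n_sses + 5)
}

#' Names of the feature-vector slots (layout version 1)
#'
#' @param n_sses SSE count N.
#' @return Character vector of length [feature_count()]`(n_sses)`.
#' @export
feature_names <- function(n_sses) {
  n <- n_sses
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  pairnm <- paste0(ij[, 1], "_", ij[, 2])
  c(
    as.vector(t(outer(pairnm, c("dist_a_", "dist_b_", "angle_a_", "angle_b_"),
                      function(p, s) paste0(s, p)))),
    as.vector(t(outer(seq_len(n), c("acc_a_", "acc_b_", "len_a_", "len_b_",
                                    "sstype_a_", "sstype_b_"),
                      function(i, s) paste0(s, i)))),
    "rmsd_dist", "rmsd_angle", "rmsd_acc", "rmsd_len",
    "identity"
  )
}

#' Feature layout metadata
#'
#' The layout of [pair_feature_vector()] is versioned so serialized models
#' and feature tables can be checked for compatibility.
#'
#' @param n_sses SSE count N.
#' @return List with `version`, `n_sses`, `m` and `names`.
#' @export
feature_layout <- function(n_sses) {
  list(version = "1", n_sses = n_sses, m = feature_count(n_sses),
       names = feature_names(n_sses))
}

rms <- function(x) sqrt(mean(x^2))

#' Feature vector of a (target, template) domain pair
#'
#' Flattens the structurally equivalent descriptors of two domains with the
#' same number of SSEs into one numeric row (layout version 1, see
#' [feature_names()]): raw pairwise distances and angles of both domains,
#' raw per-SSE accessibility/length/type of both domains, the four RMS
#' differences between the two domains' descriptor blocks, and the sequence
#' identity.
#'
#' @param dom_a,dom_b `domain_descriptors` objects (see
#'   [domain_descriptors()]) with equal `n`.
#' @param identity Sequence identity of the two domains (fraction), e.g.
#'   from [sequence_identity()].
#'
#' @return A one-row tibble with `m = feature_count(n)` named numeric
#'   columns.
#' @export
pair_feature_vector <- function(dom_a, dom_b, identity) {
  vals <- pair_feature_values(dom_a, dom_b, identity)
  as_tibble(as.list(vals))
}

# named numeric vector backing pair_feature_vector(); used directly when
# featurizing many pairs to avoid per-pair tibble overhead
pair_feature_values <- function(dom_a, dom_b, identity) {
  if (dom_a$n != dom_b$n) {
    stop("SSE count mismatch: domains being compared must have the same number of SSEs (",
         dom_a$n, " vs ", dom_b$n, ")", call. = FALSE)
  }
  pa <- dom_a$pairs; pb <- dom_b$pairs
  sa <- dom_a$per_sse; sb <- dom_b$per_sse
  vals <- c(
    as.vector(rbind(pa$distance, pb$distance, pa$angle, pb$angle)),
    as.vector(rbind(sa$accessibility, sb$accessibility,
                    sa$length, sb$length, sa$sstype, sb$sstype)),
    rms(pa$distance - pb$distance),
    rms(pa$angle - pb$angle),
    rms(sa$accessibility - sb$accessibility),
    rms(sa$length - sb$length),
    identity
  )
  stopifnot(all(is.finite(vals)))
  setNames(vals, feature_names(dom_a$n))
}
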