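# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# fixed-width PDB ATOM line for a CA-only toy structure
pdb_atom_line <- function(serial, resid3, chain, resno, x, y, z,
                          occ = 1, alt = " ", elety = "CA") {
  sprintf("ATOM  %5d %4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, sprintf(" %-3s", elety), alt, resid3, chain, resno,
          x, y, z, occ, 0)
}

write_toy_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

# a minimal DSSP-format file: header + fixed-column rows
write_toy_dssp <- function(path, rows) {
  hdr <- c("TOY HEADER",
           "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC")
  body <- vapply(rows, function(r) {
    sprintf("%5d%5d %s %s  %s%17s%4d",
            r$num, r$resno, r$chain, r$aa, r$ss, "", r$acc)
  }, "")
  writeLines(c(hdr, body), path)
  path
}

# two simple 3-SSE synthetic domains with distinct geometry
toy_domain <- function(id = "d1", shift = 0, seed = 1) {
  make_domain(
    list(
      list(kind = "helix", n_res = 8, origin = c(0, 0, 0),
           direction = c(0, 0, 1)),
      list(kind = "strand", n_res = 5, origin = c(10 + shift, 0, 0),
           direction = c(0, 1, 0)),
      list(kind = "helix", n_res = 6, origin = c(20, 5 + shift, 0),
           direction = c(1, 0, 0))
    ),
    id = id, seed = seed
  )
}

# small labelled hierarchy reused by pipeline tests
small_population <- function(seed = 5, domains = 3) {
  make_hierarchy(classes = 2, folds = 2, superfamilies = 2, families = 2,
                 domains = domains, seed = seed)
}

# brute-force run-length SSE segmentation oracle (independent of rle())
segment_oracle <- function(ss, helix_codes = "H", min_helix = 4, min_strand = 3) {
  runs <- list()
  i <- 1
  n <- length(ss)
  while (i <= n) {
    j <- i
    kind_of <- function(c) {
      if (c %in% helix_codes) "helix" else if (c == "E") "strand" else "coil"
    }
    while (j < n && kind_of(ss[j + 1]) == kind_of(ss[i])) j <- j + 1
    k <- kind_of(ss[i])
    len <- j - i + 1
    if ((k == "helix" && len >= min_helix) || (k == "strand" && len >= min_strand)) {
      runs[[length(runs) + 1L]] <- list(kind = k, start = i, end = j)
    }
    i <- j + 1
  }
  runs
}

# random rigid-body transform (proper rotation + translation)
random_rigid <- function(seed) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    list(R = q, t = rnorm(3, sd = 20))
  })
}

apply_rigid <- function(domain, rigid) {
  r <- domain$residues
  xyz <- as.matrix(r[, c("x", "y", "z")]) %*% t(rigid$R) +
    matrix(rigid$t, nrow(r), 3, byrow = TRUE)
  r$x <- xyz[, 1]; r$y <- xyz[, 2]; r$z <- xyz[, 3]
  domain$residues <- r
  domain
}

# hand-built forest whose trees are single pure leaves, for testing the
# leaf-ratio averaging arithmetic independently of training
leaf_only_forest <- function(leaf_classes, classes = c("CL", "FA")) {
  trees <- lapply(leaf_classes, function(k) {
    counts <- matrix(0, 1, length(classes))
    counts[1, match(k, classes)] <- 5
    list(feature = NA_integer_, threshold = NA_real_,
         left = 0L, right = 0L, counts = counts)
  })
  structure(
    list(trees = trees, classes = classes, feature_names = "x",
         mtry = 1L, n_train = length(leaf_classes), seed = 0L,
         split = "gain", oob_accuracy = NA_real_, layout_version = "1"),
    class = "sse_forest"
  )
}
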