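AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

unit <- function(v) v / sqrt(sum(v^2))

orthonormal_frame <- function(direction) {
  d <- unit(direction)
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit(c(d[2] * ref[3] - d[3] * ref[2],
              d[3] * ref[1] - d[1] * ref[3],
              d[1] * ref[2] - d[2] * ref[1]))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(d = d, u = u, v = v)
}

#' Generate ideal SSE C-alpha coordinates
#'
#' Places C-alpha atoms on a parameterised helical (or, with zero radius,
#' linear) curve: residue i sits at
#' `origin + rise*(i-1)*direction + radius*(cos(theta_i)*u + sin(theta_i)*v)`
#' with `theta_i = phase + twist*(i-1)` and (u, v) an orthonormal frame
#' perpendicular to `direction`. Defaults approximate an ideal alpha-helix
#' (rise 1.5 A/residue, radius 2.3 A, twist 100 deg/residue) and an extended
#' strand (rise 3.3, radius 0).
#'
#' @param kind `"helix"` or `"strand"`.
#' @param n_res Residue count (>= 4 for a helix, >= 3 for a strand).
#' @param origin 3-vector, Angstrom.
#' @param direction Axis direction (normalised internally).
#' @param rise Translation per residue along the axis, Angstrom.
#' @param radius Helix radius, Angstrom.
#' @param twist Rotation per residue, degrees.
#' @param phase Initial phase, degrees.
#' @return `n_res` x 3 coordinate matrix.
#' @export
make_sse <- function(kind = c("helix", "strand"), n_res,
                     origin = c(0, 0, 0), direction = c(0, 0, 1),
                     rise = NULL, radius = NULL, twist = NULL, phase = 0) {
  kind <- match.arg(kind)
  min_res <- if (kind == "helix") 4L else 3L
  if (n_res < min_res) {
    stop(kind, " needs at least ", min_res, " residues", call. = FALSE)
  }
  rise <- rise %||% (if (kind == "helix") 1.5 else 3.3)
  radius <- radius %||% (if (kind == "helix") 2.3 else 0)
  twist <- twist %||% (if (kind == "helix") 100 else 0)
  fr <- orthonormal_frame(direction)
  i <- seq_len(n_res) - 1
  theta <- (phase + twist * i) * pi / 180
  t(vapply(seq_len(n_res), function(k) {
    origin + rise * i[k] * fr$d +
      radius * (cos(theta[k]) * fr$u + sin(theta[k]) * fr$v)
  }, numeric(3)))
}

#' Build a synthetic annotated domain from SSE geometry specs
#'
#' Assembles a domain of exactly `length(specs)` SSEs: each spec is passed
#' to [make_sse()]; consecutive SSEs are joined by `linker` coil residues
#' interpolated linearly between them, so [segment_sses()] on the domain's
#' secondary-structure string recovers the input segmentation exactly.
#'
#' @param specs List of spec lists; each holds `kind`, `n_res` and any other
#'   [make_sse()] arguments.
#' @param id Domain identifier.
#' @param accessibility Per-residue accessibility: a single constant, a
#'   vector (recycled), or `NULL` to draw N(`acc_mean`, `acc_sd`).
#' @param acc_mean,acc_sd Parameters of the accessibility draw (A^2).
#' @param sequence Amino-acid string; `NULL` draws a random sequence.
#' @param seed Seed for random accessibility/sequence draws.
#' @param linker Number of coil residues between consecutive SSEs.
#' @return An `annotated_domain`: list with `id`, `sequence`, `residues`
#'   (tibble: `index`, `aa`, `x`, `y`, `z`, `ss`, `acc`) and `sses`
#'   (tibble from [segment_sses()]).
#' @export
make_domain <- function(specs, id = "synthetic", accessibility = NULL,
                        acc_mean = 80, acc_sd = 5, sequence = NULL,
                        seed = 1L, linker = 2L) {
  stopifnot(length(specs) >= 2L)
  coords <- list()
  ss <- character()
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    xyz <- do.call(make_sse, sp)
    if (k > 1L && linker > 0L) {
      prev_end <- coords[[length(coords)]][nrow(coords[[length(coords)]]), ]
      frac <- seq_len(linker) / (linker + 1)
      link <- t(vapply(frac, function(f) prev_end + f * (xyz[1, ] - prev_end),
                       numeric(3)))
      coords[[length(coords) + 1L]] <- link
      ss <- c(ss, rep("C", linker))
    }
    coords[[length(coords) + 1L]] <- xyz
    ss <- c(ss, rep(if (sp$kind == "helix") "H" else "E", sp$n_res))
  }
  xyz <- do.call(rbind, coords)
  n <- nrow(xyz)
  acc <- withr::with_seed(seed, {
    if (is.null(accessibility)) pmax(0, stats::rnorm(n, acc_mean, acc_sd))
    else rep_len(accessibility, n)
  })
  seq_chr <- if (is.null(sequence)) {
    withr::with_seed(seed + 1L,
                     paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = ""))
  } else {
    sequence
  }
  stopifnot(nchar(seq_chr) == n)
  residues <- tibble(
    index = seq_len(n),
    aa = strsplit(seq_chr, "")[[1]],
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    ss = ss,
    acc = acc
  )
  sses <- segment_sses(residues)
  if (nrow(sses) != length(specs)) {
    stop("internal error: segmentation recovered ", nrow(sses),
         " SSEs from ", length(specs), " specs (overlap?)", call. = FALSE)
  }
  structure(list(id = id, sequence = seq_chr, residues = residues, sses = sses),
            class = "annotated_domain")
}

#' @export
print.annotated_domain <- function(x, ...) {
  cat(sprintf("Synthetic annotated domain '%s': %d residues, %d SSEs (%s)\n",
              x$id, nrow(x$residues), nrow(x$sses),
              paste(x$sses$kind, collapse = ", ")))
  invisible(x)
}

#' SSE count of a domain
#'
#' @param domain An `annotated_domain`.
#' @return Integer N.
#' @export
n_sses <- function(domain) nrow(domain$sses)

perturb_proto <- function(proto, sigma_pos, sigma_dir) {
  lapply(proto, function(sp) {
    sp$origin <- sp$origin + stats::rnorm(3, 0, sigma_pos)
    sp$direction <- unit(sp$direction + stats::rnorm(3, 0, sigma_dir))
    sp
  })
}

mutate_sequence <- function(seq_chr, rate) {
  s <- strsplit(seq_chr, "")[[1]]
  hit <- stats::runif(length(s)) < rate
  s[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
  paste(s, collapse = "")
}

#' Simulate a domain population over a 4-level hierarchy
#'
#' Generates labelled synthetic domains whose structural similarity tracks
#' the depth of their shared level, emulating the premise that high
#' descriptor similarity implies a deep shared classification. A base
#' geometry of `sses` alternating helices/strands is perturbed by nested
#' Gaussian noise: class prototypes are drawn around the base with
#' `sigma["class"]`, fold prototypes around their class with
#' `sigma["fold"]`, and so on; each domain perturbs its family prototype
#' with `domain_scale * sigma["family"]`, so within-family descriptor RMS
#' differences shrink to 0 as `sigma["family"] -> 0`. Positional noise
#' sigma (Angstrom) also scales the axis-direction noise (`sigma/40` per
#' component) and the accessibility-mean noise, so distance, angle and
#' accessibility features are all informative. Sequences mutate a family
#' prototype at `mutation_rate` per position so the identity feature and
#' the 35% identity filter are exercised. Deterministic given `seed`.
#'
#' @param classes,folds,superfamilies,families,domains Counts per level
#'   (folds per class, superfamilies per fold, families per superfamily,
#'   domains per family).
#' @param sses SSEs per domain (all domains share this count).
#' @param sigma Named positive noise scales, strictly decreasing:
#'   `c(class=, fold=, superfamily=, family=)`, Angstrom.
#' @param domain_scale Within-family domain noise as a fraction of
#'   `sigma["family"]`.
#' @param mutation_rate Per-position sequence mutation rate within a family.
#' @param seed Integer seed.
#' @return A tibble with one row per domain: `sid`, `sccs`, `sequence`, and
#'   `domain` (list-column of `annotated_domain`).
#' @export
make_hierarchy <- function(classes = 2L, folds = 2L, superfamilies = 2L,
                           families = 2L, domains = 5L, sses = 3L,
                           sigma = c(class = 16, fold = 4,
                                     superfamily = 1, family = 0.25),
                           domain_scale = 0.25, mutation_rate = 0.8,
                           seed = 1L) {
  stopifnot(all(c(classes, folds, superfamilies, families, domains) >= 1L),
            sses >= 2L,
            all(sigma > 0), all(diff(unname(sigma)) < 0))
  kinds <- rep(c("helix", "strand"), length.out = sses)
  base_len <- ifelse(kinds == "helix", 8L, 5L)
  base <- lapply(seq_len(sses), function(k) {
    list(kind = kinds[k], n_res = base_len[k],
         origin = c(14 * (k - 1), 0, 0),
         direction = unit(c(0.2 * (k %% 2), 0.3, 1)))
  })
  withr::with_seed(seed, {
    rows <- list()
    for (ci in seq_len(classes)) {
      cl_proto <- perturb_proto(base, sigma[["class"]], sigma[["class"]] / 40)
      cl_acc <- 80 + stats::rnorm(1, 0, sigma[["class"]])
      for (fi in seq_len(folds)) {
        fo_proto <- perturb_proto(cl_proto, sigma[["fold"]], sigma[["fold"]] / 40)
        # fold-level length signature (respecting the SSE minima)
        fo_proto <- lapply(fo_proto, function(sp) {
          lo <- if (sp$kind == "helix") 4L else 3L
          sp$n_res <- max(lo, sp$n_res + sample(-1:2, 1))
          sp
        })
        fo_acc <- cl_acc + stats::rnorm(1, 0, sigma[["fold"]])
        for (si in seq_len(superfamilies)) {
          sf_proto <- perturb_proto(fo_proto, sigma[["superfamily"]],
                                    sigma[["superfamily"]] / 40)
          sf_acc <- fo_acc + stats::rnorm(1, 0, sigma[["superfamily"]])
          for (mi in seq_len(families)) {
            fa_proto <- perturb_proto(sf_proto, sigma[["family"]],
                                      sigma[["family"]] / 40)
            fa_acc <- sf_acc + stats::rnorm(1, 0, sigma[["family"]])
            n_res_total <- sum(vapply(fa_proto, `[[`, 0L, "n_res")) +
              2L * (sses - 1L)
            fa_seq <- paste(sample(AA_ALPHABET, n_res_total, replace = TRUE),
                            collapse = "")
            sccs <- sprintf("%s.%d.%d.%d", letters[ci], fi, si, mi)
            for (di in seq_len(domains)) {
              dom_proto <- perturb_proto(fa_proto,
                                         domain_scale * sigma[["family"]],
                                         domain_scale * sigma[["family"]] / 40)
              sid <- sprintf("s%s%d%d%d%02d", letters[ci], fi, si, mi, di)
              dom_seq <- mutate_sequence(fa_seq, mutation_rate)
              dom_acc_mean <- max(5, fa_acc +
                                    stats::rnorm(1, 0, domain_scale * sigma[["family"]]))
              dom <- make_domain(dom_proto, id = sid,
                                 accessibility = NULL,
                                 acc_mean = dom_acc_mean, acc_sd = 1,
                                 sequence = dom_seq,
                                 seed = sample.int(2^30, 1))
              rows[[length(rows) + 1L]] <- tibble(
                sid = sid, sccs = sccs, sequence = dom_seq, domain = list(dom)
              )
            }
          }
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

# sequence identities of all unordered pairs, batched per pattern set
all_pair_identities <- function(seqs) {
  n <- length(seqs)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(seqs[js]), seqs[i],
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5
    )
    out[i, js] <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
  }
  out
}

#' Featurize and label all domain pairs of a population
#'
#' Computes descriptors for every domain once, assembles the feature vector
#' of every unordered domain pair ([pair_feature_vector()]), derives the
#' pair type from the sccs lineages ([pair_type()]) and applies the
#' strict-below sequence-identity filter ([filter_pairs_by_identity()]).
#'
#' @param population Tibble from [make_hierarchy()] (columns `sid`, `sccs`,
#'   `sequence`, `domain`).
#' @param identity_cutoff Identity cutoff (default 0.35); `NULL` disables
#'   the filter.
#' @param acc_agg Accessibility aggregation, see [sse_geometry()].
#' @return A labelled pair table: `sid_a`, `sid_b`, `label` plus the named
#'   feature columns (including `identity`), ready for [train_forest()].
#' @export
make_pair_dataset <- function(population, identity_cutoff = 0.35,
                              acc_agg = "sum") {
  n <- nrow(population)
  stopifnot(n >= 2L)
  descs <- lapply(population$domain, domain_descriptors, acc_agg = acc_agg)
  ns <- vapply(descs, `[[`, 0L, "n")
  if (length(unique(ns)) != 1L) {
    stop("SSE count mismatch within population: ",
         paste(unique(ns), collapse = ", "), call. = FALSE)
  }
  ident <- all_pair_identities(population$sequence)
  ij <- which(upper.tri(ident), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  m <- feature_count(ns[1])
  feats <- t(vapply(seq_len(nrow(ij)), function(k) {
    pair_feature_values(descs[[ij[k, 1]]], descs[[ij[k, 2]]],
                        identity = ident[ij[k, 1], ij[k, 2]])
  }, numeric(m)))
  colnames(feats) <- feature_names(ns[1])
  out <- dplyr::bind_cols(
    tibble(
      sid_a = population$sid[ij[, 1]],
      sid_b = population$sid[ij[, 2]],
      label = pair_type(population$sccs[ij[, 1]], population$sccs[ij[, 2]])
    ),
    as_tibble(as.data.frame(feats))
  )
  if (!is.null(identity_cutoff)) {
    out <- filter_pairs_by_identity(out, identity_cutoff)
  }
  out
}

#' Write a domain's C-alpha trace as a PDB file
#'
#' Minimal single-chain PDB export (CA atoms only) for synthetic fixtures.
#'
#' @param domain An `annotated_domain`.
#' @param path Output path.
#' @param chain Chain identifier.
#' @return `path`, invisibly.
#' @export
write_domain_pdb <- function(domain, path, chain = "A") {
  r <- domain$residues
  aa3 <- bio3d::aa123(r$aa)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    r$index, aa3, chain, r$index, r$x, r$y, r$z, 1.00, 0.00
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a domain's annotations as a synthetic DSSP-format file
#'
#' Emits the fixed-column data block that [read_dssp()] consumes. This is a
#' synthetic annotation table in DSSP's file layout, not DSSP output: the
#' secondary-structure states come from the generator, not from a
#' hydrogen-bond assignment.
#'
#' @param domain An `annotated_domain`.
#' @param path Output path.
#' @param chain Chain identifier.
#' @return `path`, invisibly.
#' @export
write_domain_dssp <- function(domain, path, chain = "A") {
  r <- domain$residues
  ss <- ifelse(r$ss == "C", " ", r$ss)
  hdr <- c(
    "SYNTHETIC SECONDARY STRUCTURE ANNOTATION (DSSP FILE LAYOUT)",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA"
  )
  rows <- sprintf("%5d%5d %s %s  %s%17s%4d",
                  r$index, r$index, chain, r$aa, ss, "", round(r$acc))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Stratified train/test split of a labelled pair table
#'
#' Samples `test_fraction` of the rows of every label class into the test
#' set (rounding per class), keeping the remainder for training.
#' Deterministic given `seed`.
#'
#' @param pairs Labelled pair tibble (column `label`).
#' @param test_fraction Fraction per class assigned to the test set.
#' @param seed Integer seed.
#' @return List with tibbles `train` and `test`.
#' @export
split_pairs <- function(pairs, test_fraction = 0.3, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(pairs)), pairs$label), function(i) {
      sample(i, round(test_fraction * length(i)))
    }), use.names = FALSE)
  })
  list(train = pairs[-idx, , drop = FALSE], test = pairs[idx, , drop = FALSE])
}

#' Downsample classes to a target prevalence
#'
#' Reduces each named class to about `prevalence` of the resulting table
#' (all other classes are kept in full), emulating strongly imbalanced pair
#' sets where Fold- and Super-family-pairs are rare minority classes.
#'
#' @param pairs Labelled pair tibble (column `label`).
#' @param classes Classes to downsample.
#' @param prevalence Target fraction of the resulting table per class.
#' @param seed Integer seed.
#' @return The downsampled tibble.
#' @export
downsample_prevalence <- function(pairs, classes = c("FO", "SF"),
                                  prevalence = 0.025, seed = 1L) {
  stopifnot(prevalence > 0, prevalence < 1 / length(classes))
  n_other <- sum(!pairs$label %in% classes)
  n_total <- n_other / (1 - length(classes) * prevalence)
  per_class <- max(1L, round(prevalence * n_total))
  keep <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(pairs)), pairs$label), function(i) {
      if (pairs$label[i[1]] %in% classes && length(i) > per_class) {
        sample(i, per_class)
      } else {
        i
      }
    }), use.names = FALSE)
  })
  pairs[sort(keep), , drop = FALSE]
}
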