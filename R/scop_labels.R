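#' Parse sccs lineage strings
#'
#' An sccs string such as `"a.7.6.1"` encodes Class, Fold, Super-family and
#' Family as nested dotted prefixes: `a`, `a.7`, `a.7.6`, `a.7.6.1`.
#'
#' @param sccs Character vector of sccs strings
#'   (`letter.int.int.int`).
#' @return A tibble with columns `sccs`, `cl`, `fo`, `sf`, `fa`.
#' @export
parse_sccs <- function(sccs) {
  ok <- grepl("^[A-Za-z]\\.[0-9]+\\.[0-9]+\\.[0-9]+$", sccs)
  if (any(!ok)) {
    stop("invalid sccs string: '", sccs[which(!ok)[1]],
         "' (expected letter.int.int.int)", call. = FALSE)
  }
  parts <- strsplit(sccs, ".", fixed = TRUE)
  tibble(
    sccs = sccs,
    cl = vapply(parts, `[[`, "", 1L),
    fo = vapply(parts, function(p) paste(p[1:2], collapse = "."), ""),
    sf = vapply(parts, function(p) paste(p[1:3], collapse = "."), ""),
    fa = sccs
  )
}

#' Deepest shared SCOP level of a domain pair
#'
#' A pair is an FA-pair if the two lineages share the Family, else an
#' SF-pair if they share the Super-family, else FO (Fold), else CL (Class);
#' pairs sharing none of the four levels are NA-pairs. Vectorised and
#' symmetric in its arguments.
#'
#' @param sccs_a,sccs_b sccs strings (recycled to common length).
#' @return Character vector over the [PAIR_CLASSES] alphabet.
#' @export
pair_type <- function(sccs_a, sccs_b) {
  a <- parse_sccs(sccs_a)
  b <- parse_sccs(sccs_b)
  dplyr::case_when(
    a$fa == b$fa ~ "FA",
    a$sf == b$sf ~ "SF",
    a$fo == b$fo ~ "FO",
    a$cl == b$cl ~ "CL",
    TRUE ~ "NA"
  )
}

#' Is a lineage in a place-holder ("Not a true class") SCOP class?
#'
#' Four SCOP classes hold domains awaiting verified classification
#' (low-resolution structures, peptides, designed proteins, coiled coils);
#' by convention these carry the class letters h, i, j, k.
#'
#' @param sccs sccs strings (or bare class letters).
#' @param placeholder_set Class letters treated as place-holders.
#' @return Logical vector.
#' @export
is_placeholder_class <- function(sccs, placeholder_set = c("h", "i", "j", "k")) {
  substr(sccs, 1, 1) %in% placeholder_set
}

canonical_pair_key <- function(sid_a, sid_b) {
  paste(pmin(sid_a, sid_b), pmax(sid_a, sid_b), sep = "|")
}

#' Build one of the four train/test evaluation strategies
#'
#' Given labelled pair sets from two consecutive SCOP releases, constructs
#' the train/test split of the requested strategy:
#' \describe{
#'   \item{1}{train on all old-release pairs; test on the new-release pairs
#'     absent from the old release.}
#'   \item{2}{as 1, but NA-pairs are dropped from both sides.}
#'   \item{3}{train on the old release without its NA-pairs; test on
#'     exactly those NA-pairs.}
#'   \item{4}{train as 2; test on the NA-pairs unique to the new release.}
#' }
#' Pair identity across releases is the unordered pair of domain sids.
#'
#' @param strategy Integer 1-4.
#' @param ds_old,ds_new Tibbles of labelled pairs with columns `sid_a`,
#'   `sid_b`, `label` (plus any feature columns, carried through).
#' @return A list with tibbles `train` and `test`.
#' @export
build_strategy <- function(strategy, ds_old, ds_new) {
  stopifnot(strategy %in% 1:4)
  key_old <- canonical_pair_key(ds_old$sid_a, ds_old$sid_b)
  key_new <- canonical_pair_key(ds_new$sid_a, ds_new$sid_b)
  new_uniq <- ds_new[!key_new %in% key_old, , drop = FALSE]
  old_no_na <- ds_old[ds_old$label != "NA", , drop = FALSE]
  split <- switch(as.character(strategy),
    "1" = list(train = ds_old, test = new_uniq),
    "2" = list(train = old_no_na,
               test = new_uniq[new_uniq$label != "NA", , drop = FALSE]),
    "3" = list(train = old_no_na,
               test = ds_old[ds_old$label == "NA", , drop = FALSE]),
    "4" = list(train = old_no_na,
               test = new_uniq[new_uniq$label == "NA", , drop = FALSE])
  )
  if (strategy != 3) {
    overlap <- intersect(canonical_pair_key(split$train$sid_a, split$train$sid_b),
                         canonical_pair_key(split$test$sid_a, split$test$sid_b))
    if (length(overlap) > 0L) {
      stop("internal error: train/test overlap on ", length(overlap), " pair keys",
           call. = FALSE)
    }
  }
  split
}
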