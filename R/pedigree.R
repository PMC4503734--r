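# Pedigree-based relatedness and neighbour-group classification.
#
# Relatedness is the additive (numerator) relationship computed by the
# tabular method: individuals are processed in an order where parents
# precede offspring, with
#   A(i,i) = 1 + 0.5 * A(sire_i, dam_i)
#   A(i,j) = 0.5 * (A(j, sire_i) + A(j, dam_i))   for j already processed,
# unknown parents contributing 0. For non-inbred pairs this equals Wright's
# coefficient of relatedness r.

#' Validate a pedigree data frame
#'
#' Checks the column structure, duplicate ids and acyclicity (an individual
#' may not be its own ancestor). Parents that never appear in the `id`
#' column are treated as implicit founders.
#'
#' @param ped data frame with character columns `id`, `dam`, `sire` (`NA`
#'   for unknown).
#' @return invisibly the topological order of all ids (founders first).
#' @export
validate_pedigree <- function(ped) {
  if (!all(c("id", "dam", "sire") %in% names(ped)))
    stop("pedigree needs columns id, dam, sire", call. = FALSE)
  if (anyDuplicated(ped$id))
    stop("duplicate pedigree id(s): ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "),
         call. = FALSE)
  ids <- pedigree_closure_ids(ped)
  parents <- pedigree_parent_map(ped, ids)
  # Kahn's algorithm over the parent->offspring DAG
  indeg <- vapply(ids, function(i) sum(!is.na(parents[[i]])), integer(1))
  order_out <- character(0)
  queue <- ids[indeg == 0L]
  children <- split(rep(ped$id, 2L), f = c(ped$dam, ped$sire))
  remaining <- indeg
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order_out <- c(order_out, v)
    for (ch in children[[v]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order_out) != length(ids))
    stop("pedigree contains a cycle involving: ",
         paste(setdiff(ids, order_out), collapse = ", "), call. = FALSE)
  invisible(order_out)
}

pedigree_closure_ids <- function(ped) {
  unique(c(ped$id, stats::na.omit(ped$dam), stats::na.omit(ped$sire)))
}

pedigree_parent_map <- function(ped, ids) {
  pm <- stats::setNames(vector("list", length(ids)), ids)
  for (i in ids) pm[[i]] <- c(NA_character_, NA_character_)
  for (k in seq_len(nrow(ped)))
    pm[[ped$id[k]]] <- c(ped$dam[k], ped$sire[k])
  pm
}

#' Additive relationship matrix from a pedigree
#'
#' Tabular-method numerator relationship matrix over the pedigree closure
#' (parents referenced but not listed become founders). Diagonal entries are
#' `1 + F` (F the inbreeding coefficient); founders are pairwise unrelated.
#'
#' @param ped pedigree data frame (`id`, `dam`, `sire`; `NA` unknown).
#' @return a symmetric numeric matrix with dimnames = individual ids.
#' @export
relatedness_matrix <- function(ped) {
  topo <- validate_pedigree(ped)
  n <- length(topo)
  parents <- pedigree_parent_map(ped, topo)
  A <- matrix(0, n, n, dimnames = list(topo, topo))
  pos <- stats::setNames(seq_len(n), topo)
  for (k in seq_len(n)) {
    id <- topo[k]
    pr <- parents[[id]]
    pd <- pos[pr[1L]]; ps <- pos[pr[2L]]  # NA if unknown
    if (k > 1L) {
      earlier <- seq_len(k - 1L)
      v <- numeric(k - 1L)
      if (!is.na(pd)) v <- v + A[earlier, pd]
      if (!is.na(ps)) v <- v + A[earlier, ps]
      A[earlier, k] <- A[k, earlier] <- 0.5 * v
    }
    A[k, k] <- 1 + if (!is.na(pd) && !is.na(ps)) 0.5 * A[pd, ps] else 0
  }
  A
}

#' Pairwise relatedness of two individuals
#'
#' @param ped pedigree data frame, or a precomputed matrix from
#'   [relatedness_matrix()].
#' @param i,j individual ids (must be in the pedigree closure).
#' @return the additive relationship `A(i, j)`.
#' @export
relatedness <- function(ped, i, j) {
  A <- if (is.matrix(ped)) ped else relatedness_matrix(ped)
  for (id in c(i, j)) {
    if (!id %in% rownames(A))
      stop("individual '", id, "' not in pedigree closure", call. = FALSE)
  }
  A[i, j]
}

#' Is a neighbouring group "related" to a focal caller?
#'
#' A group counts as related when at least one of its current dominants is a
#' close relative of the caller (r at or above the threshold, default 0.25 —
#' i.e. "r = 0.25 or closer").
#'
#' @param caller caller id.
#' @param group group id.
#' @param individuals individuals data frame (see [read_individuals()]).
#' @param matrix relatedness matrix from [relatedness_matrix()].
#' @param threshold relatedness cut-off (inclusive), default 0.25.
#' @return logical.
#' @export
is_related_group <- function(caller, group, individuals, matrix,
                             threshold = 0.25) {
  doms <- individuals$id[individuals$group_id == group &
                         individuals$rank == "dominant"]
  if (!length(doms))
    stop("group '", group, "' has no recorded dominants", call. = FALSE)
  rs <- vapply(doms, function(d) rel_or_zero(matrix, caller, d), numeric(1))
  max(rs) >= threshold
}

# Individuals absent from the pedigree closure are treated as founders
# unrelated to everyone.
rel_or_zero <- function(A, i, j) {
  if (!(i %in% rownames(A)) || !(j %in% rownames(A))) return(0)
  A[i, j]
}

#' Profile a neighbouring group relative to a focal caller
#'
#' Counts the neighbour's adults (at least `adult_age_days` days
#' post-hatching at `reference_date`, inclusive), its potential breeding
#' partners (unrelated opposite-sex adults, r below the threshold) and its
#' unrelated same-sex adults, and flags whether the group is related via
#' [is_related_group()]. Individuals of unknown sex are excluded from the
#' partner and same-sex counts (but still counted as adults) and their
#' number is reported.
#'
#' @param caller caller id (sex must be known).
#' @param group neighbour group id.
#' @param individuals individuals data frame.
#' @param matrix relatedness matrix.
#' @param reference_date `Date` at which ages and membership are evaluated.
#' @param threshold relatedness cut-off (default 0.25).
#' @param adult_age_days adult age threshold in days (default 365,
#'   inclusive).
#' @return a one-row data frame: `focal_caller`, `neighbour_group`,
#'   `related`, `n_adults`, `n_potential_partners`,
#'   `n_same_sex_unrelated_adults`, `n_unknown_sex_adults`.
#' @export
profile_neighbour <- function(caller, group, individuals, matrix,
                              reference_date, threshold = 0.25,
                              adult_age_days = 365) {
  caller_sex <- individuals$sex[individuals$id == caller]
  if (!length(caller_sex) || caller_sex == "unknown")
    stop("caller '", caller, "' has unknown sex", call. = FALSE)
  reference_date <- as.Date(reference_date)
  mem <- individuals[individuals$group_id == group, , drop = FALSE]
  age_days <- as.numeric(reference_date - mem$hatch_date)
  adults <- mem[age_days >= adult_age_days, , drop = FALSE]
  r <- vapply(adults$id, function(j) rel_or_zero(matrix, caller, j), numeric(1))
  unrelated <- r < threshold
  opp <- adults$sex == setdiff(c("male", "female"), caller_sex)
  same <- adults$sex == caller_sex
  data.frame(
    focal_caller = caller,
    neighbour_group = group,
    related = if (any(mem$rank == "dominant"))
      is_related_group(caller, group, individuals, matrix, threshold) else FALSE,
    n_adults = nrow(adults),
    n_potential_partners = sum(unrelated & opp),
    n_same_sex_unrelated_adults = sum(unrelated & same),
    n_unknown_sex_adults = sum(adults$sex == "unknown"),
    stringsAsFactors = FALSE)
}
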