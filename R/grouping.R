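#' Delineate species-like groups at a distance threshold
#'
#' Partitions ASVs into "species-like groups", the operational species proxy
#' for a single marker-gene clade: clusters whose divergence does not exceed
#' a fixed Jukes-Cantor distance threshold (default 0.04, the 4% pmoA
#' species cutoff).
#'
#' Criteria:
#' \describe{
#'   \item{`tree-clade` (default)}{roots the unrooted NJ tree at the
#'     midpoint of its longest tip-to-tip path, then takes maximal clades
#'     whose within-clade maximum Jukes-Cantor tip distance is at most
#'     `threshold`.  The tree supplies the clade structure; the diameter is
#'     measured on the JC matrix because the threshold is a JC distance.}
#'   \item{`tree-clade-patristic`}{same clade search, but the diameter is
#'     the patristic (tree path) tip distance.  NJ branch fitting stretches
#'     within-group paths slightly beyond the underlying JC distances, so at
#'     the same numeric threshold this reading is systematically stricter
#'     and can split groups whose JC diameter is just under the cutoff.}
#'   \item{`complete`, `single`, `average`}{agglomerative clustering on the
#'     Jukes-Cantor matrix, cut at `threshold`.}
#' }
#' On well-separated data (within-species divergence below half the
#' threshold, between-species divergence above twice it) all four criteria
#' coincide.  Group ids (`G001`, ...) are ordered by descending total read
#' count when `counts` is supplied (falling back to group size, then the
#' lexicographically first member) so labels are stable across runs.
#'
#' @param tree Unrooted `phylo` from [nj_tree()] (required for
#'   `tree-clade`; ignored otherwise).
#' @param dm Jukes-Cantor distance matrix over the same ASVs.
#' @param threshold Distance threshold > 0 (default 0.04).
#' @param criterion One of `"tree-clade"`, `"tree-clade-patristic"`,
#'   `"complete"`, `"single"`, `"average"`.
#' @param counts Optional [asv_table] (or ASV-by-sample matrix) used to
#'   order group ids by abundance.
#' @return A tibble of class `group_assignment` with columns `asv_id`,
#'   `group_id`; attributes `threshold`, `criterion` and `groups` (a
#'   per-group tibble `group_id`, `n_asvs`, `diameter`, where `diameter` is
#'   the maximal within-group distance used by the criterion: JC for
#'   `tree-clade`, patristic for `tree-clade-patristic`, the linkage merge
#'   height otherwise).
#' @export
cut_into_groups <- function(tree = NULL, dm, threshold = 0.04,
                            criterion = c("tree-clade", "tree-clade-patristic",
                                          "complete", "single", "average"),
                            counts = NULL) {
  criterion <- match.arg(criterion)
  if (threshold <= 0) abort("`threshold` must be positive")
  dm <- as.matrix(dm)
  labels <- rownames(dm)
  if (criterion %in% c("tree-clade", "tree-clade-patristic")) {
    if (is.null(tree)) abort("the tree-clade criteria need a tree")
    missing <- setdiff(tree$tip.label, labels)
    if (length(missing)) {
      abort(sprintf("tree tips missing from the distance matrix: %s",
                    paste(head(missing, 3L), collapse = ", ")))
    }
    measure <- if (criterion == "tree-clade") {
      dm[tree$tip.label, tree$tip.label, drop = FALSE]
    } else {
      patristic_distances(tree)
    }
    res <- cut_tree_clades(tree, measure, threshold)
  } else {
    res <- cut_linkage(dm, threshold, criterion)
  }
  membership <- res$membership   # named integer vector, cluster index per ASV
  diam <- res$diameter           # per cluster index
  ids <- order_group_ids(membership, counts)
  groups <- tibble(
    group_id = unname(ids[as.character(seq_along(diam))]),
    n_asvs = as.integer(table(membership)[as.character(seq_along(diam))]),
    diameter = diam
  ) |> arrange(.data$group_id)
  out <- tibble(
    asv_id = names(membership),
    group_id = unname(ids[as.character(membership)])
  )
  attr(out, "threshold") <- threshold
  attr(out, "criterion") <- criterion
  attr(out, "groups") <- groups
  class(out) <- c("group_assignment", class(out))
  out
}

# Midpoint-root the tree, then collect maximal clades whose tip diameter
# under `measure` is <= threshold (every tip alone always satisfies it).
cut_tree_clades <- function(tree, measure, threshold) {
  pat <- measure
  if (length(tree$tip.label) == 1L) {
    return(list(membership = setNames(1L, tree$tip.label), diameter = 0))
  }
  rooted <- phangorn::midpoint(tree)
  n_tip <- length(rooted$tip.label)
  children <- split(rooted$edge[, 2L], rooted$edge[, 1L])
  tips_under <- function(node) {
    if (node <= n_tip) return(rooted$tip.label[node])
    unlist(lapply(children[[as.character(node)]], tips_under), use.names = FALSE)
  }
  clusters <- list()
  visit <- function(node) {
    tips <- tips_under(node)
    d <- if (length(tips) == 1L) 0 else max(pat[tips, tips])
    if (d <= threshold) {
      clusters[[length(clusters) + 1L]] <<- list(tips = tips, diameter = d)
    } else {
      for (ch in children[[as.character(node)]]) visit(ch)
    }
  }
  visit(n_tip + 1L)
  membership <- integer(0)
  for (i in seq_along(clusters)) {
    membership[clusters[[i]]$tips] <- i
  }
  list(membership = membership[rooted$tip.label],
       diameter = vapply(clusters, `[[`, numeric(1), "diameter"))
}

cut_linkage <- function(dm, threshold, method) {
  if (nrow(dm) == 1L) {
    return(list(membership = setNames(1L, rownames(dm)), diameter = 0))
  }
  hc <- hclust(as.dist(dm), method = method)
  membership <- cutree(hc, h = threshold)
  diam <- vapply(sort(unique(membership)), function(g) {
    members <- names(membership)[membership == g]
    if (length(members) == 1L) return(0)
    # linkage height actually used by the criterion = height of the last
    # merge internal to the group
    max_internal_merge_height(hc, members, membership)
  }, numeric(1))
  list(membership = membership, diameter = diam)
}

# height of the highest hclust merge whose two children both lie inside the
# given group (the linkage distance the cut criterion actually compared)
max_internal_merge_height <- function(hc, members, membership) {
  lab <- hc$labels
  in_group <- lab %in% members
  node_in <- logical(nrow(hc$merge))
  best <- 0
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1L]
    b <- hc$merge[i, 2L]
    a_in <- if (a < 0) in_group[-a] else node_in[a]
    b_in <- if (b < 0) in_group[-b] else node_in[b]
    node_in[i] <- a_in && b_in
    if (node_in[i]) best <- max(best, hc$height[i])
  }
  best
}

order_group_ids <- function(membership, counts) {
  idx <- sort(unique(membership))
  weight <- if (!is.null(counts)) {
    mat <- if (inherits(counts, "asv_table")) counts$counts else as.matrix(counts)
    totals <- rowSums(mat)[names(membership)]
    totals[is.na(totals)] <- 0
    vapply(idx, function(g) sum(totals[membership == g]), numeric(1))
  } else {
    vapply(idx, function(g) sum(membership == g), numeric(1))
  }
  first_member <- vapply(
    idx, function(g) min(names(membership)[membership == g]), ""
  )
  ord <- order(-weight, first_member)
  ids <- setNames(character(length(idx)), as.character(idx))
  ids[as.character(idx[ord])] <- sprintf("G%03d", seq_along(idx))
  ids
}

#' @export
print.group_assignment <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf(
    "<group_assignment> %d ASVs in %d species-like groups (threshold %.3f, %s)\n",
    nrow(x), nrow(g), attr(x, "threshold"), attr(x, "criterion")
  ))
  NextMethod()
}

#' Per-group summary of a group assignment
#'
#' @param assign A `group_assignment` from [cut_into_groups()].
#' @return The per-group tibble (`group_id`, `n_asvs`, `diameter`).
#' @export
group_summary <- function(assign) attr(assign, "groups")

#' Group-by-sample count matrix
#'
#' Sums member ASV counts within each species-like group.
#'
#' @param assign A `group_assignment`.
#' @param x An [asv_table] whose ASVs are all assigned.
#' @return Integer matrix, groups in rows (ordered by group id), samples in
#'   columns.
#' @export
group_counts <- function(assign, x) {
  stopifnot(inherits(x, "asv_table"))
  unassigned <- setdiff(rownames(x$counts), assign$asv_id)
  if (length(unassigned)) {
    abort(sprintf("unassigned ASVs in the count table: %s",
                  paste(head(unassigned, 3L), collapse = ", ")))
  }
  g <- assign$group_id[match(rownames(x$counts), assign$asv_id)]
  out <- rowsum(x$counts, g)
  out[order(rownames(out)), , drop = FALSE]
}

#' Relative group composition per sample or per site
#'
#' Converts group counts to relative abundances per sample; optionally
#' averages the relative abundances over a site's replicates (arithmetic
#' mean), the representation used for composite heatmaps.
#'
#' @param assign A `group_assignment`.
#' @param x An [asv_table].
#' @param average_replicates Average replicate profiles within each site?
#' @return A tibble `group_id`, `sample` (or `site`), `abundance`; within
#'   each sample/site the abundances sum to 1.  Samples with zero clade
#'   reads are dropped and listed in the `"absent_samples"` attribute.
#' @export
composition_matrix <- function(assign, x, average_replicates = FALSE) {
  gc <- group_counts(assign, x)
  totals <- colSums(gc)
  absent <- colnames(gc)[totals == 0]
  if (length(absent)) {
    warn(sprintf("dropping zero-count sample(s): %s", paste(absent, collapse = ", ")))
    gc <- gc[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  rel <- sweep(gc, 2L, totals, "/")
  long <- as_tibble(rel, rownames = "group_id") |>
    tidyr::pivot_longer(-"group_id", names_to = "sample", values_to = "abundance")
  out <- if (average_replicates) {
    long |>
      left_join(x$samples, by = "sample") |>
      group_by(.data$group_id, .data$site) |>
      summarise(abundance = mean(.data$abundance), .groups = "drop")
  } else {
    long
  }
  attr(out, "absent_samples") <- absent
  attr(out, "mode") <- if (average_replicates) "site-averaged" else "per-sample"
  out
}

#' Detection prevalence of groups across sites and samples
#'
#' For each group, counts the sites and samples where it is detected
#' (relative abundance strictly above `detection_floor` in at least one
#' replicate), and classifies groups as multi-site, all-site, single-site
#' and single-sample — the prevalence breakdown used to describe how widely
#' each species-like group occurs.
#'
#' @param assign A `group_assignment`.
#' @param x An [asv_table].
#' @param detection_floor Relative-abundance detection limit (default 0:
#'   any nonzero read counts as detection).
#' @return A tibble with one row per group: `group_id`, `n_sites_detected`,
#'   `n_samples_detected`, `in_all_sites`, `multi_site`, `single_site`,
#'   `single_sample`; total site count in attribute `"n_sites"`.
#' @export
prevalence_summary <- function(assign, x, detection_floor = 0) {
  comp <- composition_matrix(assign, x, average_replicates = FALSE) |>
    left_join(x$samples, by = "sample")
  n_sites <- length(unique(x$samples$site))
  out <- comp |>
    group_by(.data$group_id) |>
    summarise(
      n_sites_detected = dplyr::n_distinct(.data$site[.data$abundance > detection_floor]),
      n_samples_detected = sum(.data$abundance > detection_floor),
      .groups = "drop"
    ) |>
    mutate(
      in_all_sites = .data$n_sites_detected == n_sites,
      multi_site = .data$n_sites_detected > 1L,
      single_site = .data$n_sites_detected == 1L,
      single_sample = .data$n_samples_detected == 1L
    )
  attr(out, "n_sites") <- n_sites
  out
}

#' Place a reference sequence into an existing grouping
#'
#' Assigns a reference marker sequence (e.g. a database endosymbiont pmoA)
#' to the species-like group of its nearest ASV if that nearest Jukes-Cantor
#' distance is within the threshold, else reports it as ungrouped.
#'
#' @param ref_seq Reference nucleotide sequence, trimmed to the same region
#'   and length as the ASVs.
#' @param x An [asv_table].
#' @param assign A `group_assignment` over the table's ASVs.
#' @param threshold Distance threshold (default the assignment's own).
#' @return A one-row tibble: `group_id` (or `"ungrouped"`), `nearest_asv`,
#'   `distance`.
#' @export
place_reference <- function(ref_seq, x, assign,
                            threshold = attr(assign, "threshold")) {
  stopifnot(inherits(x, "asv_table"))
  if (nchar(ref_seq) != nchar(x$sequences[[1L]])) {
    abort("reference length differs from the ASV region length")
  }
  # saturated pairs (p >= 0.75) have no finite JC distance; they are
  # certainly beyond any grouping threshold, so treat them as infinitely far
  d <- vapply(x$sequences, function(s) {
    p <- p_distance(ref_seq, s)
    if (p >= 0.75) Inf else jc_correction(p)
  }, numeric(1))
  nearest <- names(d)[which.min(d)]
  dist <- min(d)
  gid <- if (dist <= threshold) {
    assign$group_id[match(nearest, assign$asv_id)]
  } else {
    "ungrouped"
  }
  tibble(group_id = gid, nearest_asv = nearest, distance = dist)
}
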