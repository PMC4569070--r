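#' Shortest correlated-motion pathways between two residue sets
#'
#' Enumerates all shortest paths between every (source, target) residue pair
#' in a correlation network, discards paths longer than the length bound
#' implied by the threshold (see [max_pathway_length()]), and summarizes how
#' often each residue is traversed. Residues on 100% of the retained paths
#' form the bottleneck through which all correlated motion between the two
#' sites is channelled.
#'
#' @param graph an igraph network from [build_network()].
#' @param source,target disjoint vertex sets (names or indices).
#' @param r_crit the LMI threshold used to build the graph; sets the length
#'   bound. Alternatively give `max_len` directly.
#' @param max_len optional explicit maximum path length (edges).
#' @return object of class `pathway_result`: list with `paths` (list of
#'   vertex-name vectors), `pairs` (data.frame of source/target/distance/
#'   n_paths per connected pair), `fraction_paths` (per residue, fraction of
#'   all retained paths traversing it), `fraction_pairs` (per residue,
#'   fraction of connected pairs with at least one traversing path),
#'   `bottleneck` (residues with `fraction_paths == 1`), `max_len`.
#'   Endpoint residues are included in the fractions. Empty `paths` signals
#'   disconnection at this threshold.
#' @export
find_pathways <- function(graph, source, target, r_crit = NULL, max_len = NULL) {
  vn <- igraph::V(graph)$name
  if (is.null(vn)) vn <- as.character(seq_len(igraph::vcount(graph)))
  source <- as.character(source); target <- as.character(target)
  if (length(intersect(source, target))) {
    stop("source and target sets must be disjoint", call. = FALSE)
  }
  missing <- setdiff(c(source, target), vn)
  if (length(missing)) {
    stop(sprintf("vertices not in the network: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(max_len)) {
    if (is.null(r_crit)) stop("give either r_crit or max_len", call. = FALSE)
    max_len <- max_pathway_length(r_crit)
  }
  paths <- list()
  pair_rows <- list()
  for (s in source) {
    sp <- suppressWarnings(igraph::all_shortest_paths(graph, from = s, to = target))
    # group the returned paths by their endpoint
    ends <- vapply(sp$res, function(p) vn[as.integer(p[length(p)])], character(1))
    for (t in target) {
      ps <- sp$res[ends == t]
      if (!length(ps)) next
      lens <- vapply(ps, length, integer(1)) - 1L
      if (lens[1] > max_len) next
      for (p in ps) paths[[length(paths) + 1L]] <- vn[as.integer(p)]
      pair_rows[[length(pair_rows) + 1L]] <-
        data.frame(source = s, target = t, distance = lens[1],
                   n_paths = length(ps), stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(source = character(0), target = character(0),
               distance = integer(0), n_paths = integer(0))
  if (!length(paths)) {
    return(structure(list(paths = list(), pairs = pairs,
                          fraction_paths = numeric(0), fraction_pairs = numeric(0),
                          bottleneck = character(0), max_len = max_len),
                     class = "pathway_result"))
  }
  all_res <- sort(unique(unlist(paths)))
  on_path <- vapply(all_res, function(r) {
    sum(vapply(paths, function(p) r %in% p, logical(1)))
  }, numeric(1))
  fraction_paths <- on_path / length(paths)
  pair_of_path <- rep(seq_len(nrow(pairs)), pairs$n_paths)
  fraction_pairs <- vapply(all_res, function(r) {
    hit <- vapply(paths, function(p) r %in% p, logical(1))
    length(unique(pair_of_path[hit])) / nrow(pairs)
  }, numeric(1))
  structure(list(paths = paths, pairs = pairs,
                 fraction_paths = fraction_paths,
                 fraction_pairs = fraction_pairs,
                 bottleneck = names(fraction_paths)[fraction_paths == 1],
                 max_len = max_len),
            class = "pathway_result")
}

#' @export
print.pathway_result <- function(x, ...) {
  if (!length(x$paths)) {
    cat("<pathway_result> no pathways within the length bound (disconnected)\n")
  } else {
    cat(sprintf("<pathway_result> %d shortest paths over %d pairs (max length %s); bottleneck: %s\n",
                length(x$paths), nrow(x$pairs), format(x$max_len),
                if (length(x$bottleneck)) paste(x$bottleneck, collapse = ", ") else "none"))
  }
  invisible(x)
}

#' Scan the LMI threshold down until two sites connect
#'
#' Starting from `r_start`, lowers the threshold in steps and returns the
#' first (largest) value at which at least one pathway within the length
#' bound joins the source and target sets.
#'
#' @param lmi an [lmi_matrix()].
#' @param source,target disjoint residue sets.
#' @param r_start starting threshold.
#' @param step decrement per scan step.
#' @param r_floor lowest threshold scanned (exclusive stop).
#' @return list with `r_crit` (first connecting threshold, `NA` if never),
#'   `connected`, `n_paths`, `scanned` (thresholds tried).
#' @export
threshold_scan <- function(lmi, source, target, r_start = 1, step = 0.05,
                           r_floor = 0) {
  stopifnot(r_start > 0, step > 0)
  scanned <- numeric(0)
  r <- r_start
  while (r > r_floor + 1e-12) {
    scanned <- c(scanned, r)
    g <- build_network(lmi, r)
    pw <- find_pathways(g, source, target, r_crit = r)
    if (length(pw$paths)) {
      return(list(r_crit = r, connected = TRUE, n_paths = length(pw$paths),
                  scanned = scanned))
    }
    r <- r - step
  }
  list(r_crit = NA_real_, connected = FALSE, n_paths = 0L, scanned = scanned)
}

#' Residue pairs separated by at least a minimum distance
#'
#' Control-pathway enumeration considers all residue pairs whose C-alpha
#' atoms are at least `min_sep` apart (default 60 Angstrom = 6 nm).
#'
#' @param traj a [ca_trajectory()] (frame 1 is used) or an N x 3 coordinate
#'   matrix, in Angstrom.
#' @param min_sep minimum separation in the coordinate units (default 60).
#' @return data.frame with columns `i`, `j` (residue indices, `i < j`),
#'   `label_i`, `label_j`, `distance`.
#' @export
control_pairs <- function(traj, min_sep = 60) {
  if (inherits(traj, "fib_traj")) {
    pts <- xyz_to_mat(traj$xyz[1, ])
    labels <- paste(traj$top$chain, traj$top$resno, sep = "_")
  } else {
    pts <- as.matrix(traj)
    labels <- paste0("res_", seq_len(nrow(pts)))
  }
  d <- as.matrix(stats::dist(pts))
  sel <- which(upper.tri(d) & d >= min_sep, arr.ind = TRUE)
  out <- data.frame(i = sel[, 1], j = sel[, 2],
                    label_i = labels[sel[, 1]], label_j = labels[sel[, 2]],
                    distance = d[sel], stringsAsFactors = FALSE)
  out[order(out$i, out$j), , drop = FALSE]
}
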