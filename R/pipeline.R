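#' Read and write complex definition files
#'
#' Membership files are tab-separated with one line per complex: the complex
#' id followed by its member identifiers (duplicates collapsed).  Reference
#' files carry one internal edge per line (`complex_id TAB protein_a TAB
#' protein_b`); membership is implied by the edge endpoints, and an optional
#' line `complex_id TAB MEMBERS TAB p1 TAB p2 ...` adds members that occur
#' in no reference edge.
#'
#' @param path file path.
#' @return list of [complex_definition()]s (empty file gives an empty list).
#' @export
read_complexes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    f <- trimws(f)
    if (length(f) < 2) {
      stop(sprintf("line %d of %s: a complex needs an id and at least one member",
                   i, path), call. = FALSE)
    }
    complex_definition(f[1], f[-1])
  })
  out
}

#' @rdname read_complexes
#' @export
read_reference_complexes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  edges <- list()
  extra_members <- list()
  order_seen <- character()
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    if (length(f) < 3) {
      stop(sprintf("line %d of %s: need complex_id and an edge or MEMBERS list",
                   i, path), call. = FALSE)
    }
    id <- f[1]
    if (!(id %in% order_seen)) order_seen <- c(order_seen, id)
    if (f[2] == "MEMBERS") {
      extra_members[[id]] <- c(extra_members[[id]], f[-(1:2)])
    } else {
      edges[[id]] <- rbind(edges[[id]], f[2:3])
    }
  }
  lapply(order_seen, function(id) {
    ed <- edges[[id]]
    members <- unique(c(as.character(ed), extra_members[[id]]))
    complex_definition(id, members, reference_edges = ed)
  })
}

#' @rdname read_complexes
#' @param complexes list of [complex_definition()]s.
#' @export
write_complexes <- function(complexes, path) {
  lines <- vapply(complexes, function(cx) {
    paste(c(cx$complex_id, cx$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_complexes
#' @export
write_reference_complexes <- function(complexes, path) {
  lines <- unlist(lapply(complexes, function(cx) {
    ed <- cx$reference_edges
    edge_lines <- if (!is.null(ed) && nrow(ed)) {
      paste(cx$complex_id, ed[, 1], ed[, 2], sep = "\t")
    } else character()
    loose <- setdiff(cx$members, as.character(ed))
    member_line <- if (length(loose)) {
      paste(c(cx$complex_id, "MEMBERS", loose), collapse = "\t")
    } else character()
    c(edge_lines, member_line)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Survey every complex in a network
#'
#' Profiles each complex's induced graph and its subgraph variants, records
#' which complexes have no member in the network and which induce no edge at
#' all (the "no interaction" list, excluded from all threshold sweeps), and
#' optionally draws matched pseudocomplexes as a per-complex null.
#'
#' @param network interaction network.
#' @param complexes list of [complex_definition()]s.
#' @param pseudo_cfg optional [pseudocomplex_config()]; when given, matched
#'   pseudocomplexes are sampled and profiled.
#' @return list of class `survey_result` with fields `profiles` (named list
#'   of `variant_profiles` for every complex with >= 1 member present),
#'   `eligible_ids` (complexes with >= 1 induced edge; the sweep universe),
#'   `no_interaction_ids`, `absent_ids`, `pseudo` (or NULL).
#' @export
run_survey <- function(network, complexes, pseudo_cfg = NULL) {
  if (igraph::vcount(network) == 0L) stop("network is empty", call. = FALSE)
  ids <- vapply(complexes, function(cx) cx$complex_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate complex ids", call. = FALSE)
  profiles <- list()
  eligible <- character()
  no_interaction <- character()
  absent <- character()
  for (cx in complexes) {
    g <- complex_graph(network, cx$members)
    if (igraph::vcount(g) == 0L) {
      absent <- c(absent, cx$complex_id)
      next
    }
    profiles[[cx$complex_id]] <- variant_profiles(network, cx)
    if (igraph::ecount(g) == 0L) {
      no_interaction <- c(no_interaction, cx$complex_id)
    } else {
      eligible <- c(eligible, cx$complex_id)
    }
  }
  pseudo <- NULL
  if (!is.null(pseudo_cfg)) {
    pseudo <- matched_pseudocomplexes(network, complexes, pseudo_cfg)
  }
  structure(list(profiles = profiles, eligible_ids = eligible,
                 no_interaction_ids = no_interaction, absent_ids = absent,
                 pseudo = pseudo),
            class = "survey_result")
}

# statistics understood by sweeps and comparisons, mapped onto profile fields.
# `mhcs_k` is resolved at the variant_profiles level, everything else on a
# single topology_profile; undefined values come back NA.
.sweep_statistics <- c("edge_density", "vertex_connectivity",
  "edge_connectivity", "clustering_coefficient", "mcc_mean", "mcc_max",
  "degree_max", "degree_mean", "betweenness_max", "betweenness_mean",
  "triangle_count", "four_cycle_count")

.stat_from_profile <- function(p, statistic) {
  if (is.null(p)) return(NA_real_)
  switch(statistic,
    edge_density = p$edge_density,
    vertex_connectivity = as.numeric(p$vertex_connectivity),
    edge_connectivity = as.numeric(p$edge_connectivity),
    clustering_coefficient =
      if (isTRUE(p$cc_defined)) p$clustering_coefficient else NA_real_,
    mcc_mean = p$mcc_stats$mean,
    mcc_max = p$mcc_stats$maximum,
    degree_max = p$degree_stats$maximum,
    degree_mean = p$degree_stats$mean,
    betweenness_max = p$betweenness_stats$maximum,
    betweenness_mean = p$betweenness_stats$mean,
    triangle_count = as.numeric(p$triangle_count),
    four_cycle_count = as.numeric(p$four_cycle_count),
    stop(sprintf("unknown statistic '%s'", statistic), call. = FALSE))
}

.variant_stat <- function(vp, variant, statistic) {
  p <- switch(variant, full = vp$full, haircut = vp$haircut, mhcs = vp$mhcs)
  .stat_from_profile(p, statistic)
}

# percent of values meeting the threshold; NA (undefined) never passes but
# stays in the denominator
.percent_passing <- function(values, thr, direction) {
  if (length(values) == 0L) return(NA_real_)
  pass <- if (direction == "above") values >= thr else values <= thr
  100 * sum(pass, na.rm = TRUE) / length(values)
}

#' Threshold sweep of one statistic
#'
#' For an ordered grid of thresholds, computes the percent of eligible
#' complexes whose statistic is at or above (`direction = "above"`) or at or
#' below (`"below"`; used for betweenness) each threshold, separately for
#' the full complex graph, the haircut graph, the MHCS, all connected
#' components pooled, and — when the survey carried pseudocomplexes — the
#' pooled pseudocomplex samples.  Undefined values (empty haircut, undefined
#' betweenness, ...) never count as passing.
#'
#' @param result a [run_survey()] result.
#' @param statistic one of `"edge_density"`, `"vertex_connectivity"`,
#'   `"edge_connectivity"`, `"clustering_coefficient"`, `"mcc_mean"`,
#'   `"mcc_max"`, `"degree_max"`, `"degree_mean"`, `"betweenness_max"`,
#'   `"betweenness_mean"`, `"triangle_count"`, `"four_cycle_count"`.
#' @param thresholds numeric grid (sorted internally).
#' @param direction `"above"` or `"below"`.
#' @param pseudo_variant which variant of each pseudocomplex supplies the
#'   pseudo series (default `"full"`; comparisons of connectivity are more
#'   informative on `"mhcs"`).
#' @return data frame of class `sweep_table` with columns `statistic`,
#'   `direction`, `threshold`, `percent_full`, `percent_haircut`,
#'   `percent_mhcs`, `percent_components`, and `percent_pseudo` when
#'   available.
#' @export
threshold_sweep <- function(result, statistic, thresholds,
                            direction = c("above", "below"),
                            pseudo_variant = c("full", "mhcs", "haircut")) {
  direction <- match.arg(direction)
  pseudo_variant <- match.arg(pseudo_variant)
  stopifnot(inherits(result, "survey_result"))
  statistic <- match.arg(statistic, .sweep_statistics)
  thresholds <- sort(thresholds)
  vps <- result$profiles[result$eligible_ids]
  vals <- list(
    full = vapply(vps, .variant_stat, numeric(1), variant = "full",
                  statistic = statistic),
    haircut = vapply(vps, .variant_stat, numeric(1), variant = "haircut",
                     statistic = statistic),
    mhcs = vapply(vps, .variant_stat, numeric(1), variant = "mhcs",
                  statistic = statistic),
    components = unlist(lapply(vps, function(vp) {
      vapply(vp$components, .stat_from_profile, numeric(1),
             statistic = statistic)
    }), use.names = FALSE))
  out <- data.frame(
    statistic = statistic, direction = direction, threshold = thresholds,
    percent_full = vapply(thresholds, .percent_passing, numeric(1),
                          values = vals$full, direction = direction),
    percent_haircut = vapply(thresholds, .percent_passing, numeric(1),
                             values = vals$haircut, direction = direction),
    percent_mhcs = vapply(thresholds, .percent_passing, numeric(1),
                          values = vals$mhcs, direction = direction),
    percent_components = vapply(thresholds, .percent_passing, numeric(1),
                                values = vals$components, direction = direction),
    stringsAsFactors = FALSE)
  if (!is.null(result$pseudo) && length(result$pseudo)) {
    pvals <- unlist(lapply(result$pseudo, function(samples) {
      vapply(samples, .variant_stat, numeric(1), variant = pseudo_variant,
             statistic = statistic)
    }), use.names = FALSE)
    out$percent_pseudo <- vapply(thresholds, .percent_passing, numeric(1),
                                 values = pvals, direction = direction)
  }
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Compare real complexes with their matched pseudocomplexes
#'
#' For each surveyed statistic (on the full graph) and for the MHCS
#' connectivity, reports the mean over real complexes that have matched
#' pseudocomplexes, the mean and population standard deviation over all
#' pooled pseudocomplex samples, and the separation
#' `(real_mean - pseudo_mean) / pseudo_sd` (NA when the pseudo sd is 0).
#'
#' @param result a [run_survey()] result that carried pseudocomplexes.
#' @return data frame with columns `statistic`, `variant`, `real_mean`,
#'   `pseudo_mean`, `pseudo_sd`, `separation`.
#' @export
compare_with_pseudocomplexes <- function(result) {
  stopifnot(inherits(result, "survey_result"))
  if (is.null(result$pseudo) || length(result$pseudo) == 0L) {
    stop("survey carries no pseudocomplex profiles", call. = FALSE)
  }
  matched_ids <- intersect(names(result$pseudo), names(result$profiles))
  rows <- lapply(c(.sweep_statistics, "mhcs_k"), function(statistic) {
    if (statistic == "mhcs_k") {
      real <- vapply(result$profiles[matched_ids], function(vp) {
        as.numeric(vp$mhcs_k)
      }, numeric(1))
      pseudo <- unlist(lapply(result$pseudo[matched_ids], function(samples) {
        vapply(samples, function(vp) as.numeric(vp$mhcs_k), numeric(1))
      }), use.names = FALSE)
      variant <- "mhcs"
    } else {
      real <- vapply(result$profiles[matched_ids], .variant_stat, numeric(1),
                     variant = "full", statistic = statistic)
      pseudo <- unlist(lapply(result$pseudo[matched_ids], function(samples) {
        vapply(samples, .variant_stat, numeric(1), variant = "full",
               statistic = statistic)
      }), use.names = FALSE)
      variant <- "full"
    }
    pm <- mean(pseudo, na.rm = TRUE)
    psd <- sqrt(mean((pseudo - pm)^2, na.rm = TRUE))
    rm_ <- mean(real, na.rm = TRUE)
    data.frame(statistic = statistic, variant = variant,
               real_mean = rm_, pseudo_mean = pm, pseudo_sd = psd,
               separation = if (!is.na(psd) && psd > 0) (rm_ - pm) / psd
                            else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# per-variant result table: one row per complex carrying that variant,
# connected complexes listed before unconnected, then by id
.variant_table <- function(result, variant) {
  ids <- result$eligible_ids
  rows <- lapply(ids, function(id) {
    vp <- result$profiles[[id]]
    p <- switch(variant, normal = vp$full, haircut = vp$haircut,
                max_connect = vp$mhcs)
    if (is.null(p)) return(NULL)
    cbind(data.frame(complex_id = id, coverage = vp$coverage,
                     mhcs_k = vp$mhcs_k, stringsAsFactors = FALSE),
          profile_row(p))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- cbind(data.frame(complex_id = character(), coverage = numeric(),
                            mhcs_k = integer(), stringsAsFactors = FALSE),
                 stats::setNames(as.data.frame(matrix(numeric(), ncol = length(.profile_cols))),
                                 .profile_cols))
  } else {
    tab <- tab[order(-tab$is_connected, tab$complex_id), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write survey results as TSV tables
#'
#' Writes `normal.tsv`, `haircut.tsv` and `max_connect.tsv` (one row per
#' complex per non-empty variant, connected complexes listed before
#' unconnected ones), `no_interaction.tsv` (complexes whose members induce
#' no edge), default threshold sweeps (`sweep_<statistic>.tsv`; betweenness
#' swept downward, connectivity over k = 1..6, all other statistics over
#' 0-1 in steps of 0.1), and `pseudo_comparison.tsv` when the survey carried
#' pseudocomplexes.  Reruns from the same survey are byte-identical.
#'
#' @param result a [run_survey()] result.
#' @param outdir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(result, outdir) {
  stopifnot(inherits(result, "survey_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (variant in c("normal", "haircut", "max_connect")) {
    path <- file.path(outdir, paste0(variant, ".tsv"))
    .write_tsv(.variant_table(result, variant), path)
    files <- c(files, path)
  }
  ni <- data.frame(complex_id = result$no_interaction_ids,
                   stringsAsFactors = FALSE)
  path <- file.path(outdir, "no_interaction.tsv")
  .write_tsv(ni, path)
  files <- c(files, path)
  grids <- .default_sweep_grids()
  for (statistic in names(grids)) {
    sw <- threshold_sweep(result, statistic, grids[[statistic]]$thresholds,
                          direction = grids[[statistic]]$direction,
                          pseudo_variant = grids[[statistic]]$pseudo_variant)
    path <- file.path(outdir, paste0("sweep_", statistic, ".tsv"))
    .write_tsv(sw, path)
    files <- c(files, path)
  }
  if (!is.null(result$pseudo) && length(result$pseudo)) {
    path <- file.path(outdir, "pseudo_comparison.tsv")
    .write_tsv(compare_with_pseudocomplexes(result), path)
    files <- c(files, path)
  }
  invisible(files)
}

.default_sweep_grids <- function() {
  unit <- seq(0, 1, by = 0.1)
  list(
    edge_density = list(thresholds = unit, direction = "above",
                        pseudo_variant = "full"),
    vertex_connectivity = list(thresholds = 1:6, direction = "above",
                               pseudo_variant = "mhcs"),
    clustering_coefficient = list(thresholds = unit, direction = "above",
                                  pseudo_variant = "full"),
    mcc_mean = list(thresholds = unit, direction = "above",
                    pseudo_variant = "full"),
    degree_max = list(thresholds = unit, direction = "above",
                      pseudo_variant = "full"),
    betweenness_max = list(thresholds = unit, direction = "below",
                           pseudo_variant = "full"))
}
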