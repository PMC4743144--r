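#' Structural model for a planted complex
#'
#' Three wiring models for a complex's internal interactions:
#' * `ring_lattice(size, b)`: members on a cycle, each bound to its `b`
#'   nearest neighbors on each side.  This realizes the steric-constraint
#'   picture of a densely packed complex — every protein binds a bounded
#'   number of neighbors regardless of complex size — so edge density
#'   `2b/(size-1)` falls as the complex grows while vertex connectivity
#'   stays constant at `2b` (for `size >= 2b + 2`).
#' * `clique`: every pair bound (small complexes often look like this).
#' * `hub_spoke`: one central protein bound to all others, no rim edges (the
#'   "star" pattern seen around high-degree proteins).
#'
#' @param model `"ring_lattice"`, `"clique"` or `"hub_spoke"`.
#' @param size number of members (>= 3; ring_lattice needs
#'   `size >= 2 * binding_width + 2`).
#' @param binding_width neighbors bound on each side (ring_lattice only).
#' @export
complex_model_spec <- function(model = c("ring_lattice", "clique", "hub_spoke"),
                               size, binding_width = 2L) {
  model <- match.arg(model)
  size <- as.integer(size)
  binding_width <- as.integer(binding_width)
  if (size < 3) stop("complex size must be at least 3", call. = FALSE)
  if (model == "ring_lattice") {
    if (binding_width < 1) stop("binding_width must be >= 1", call. = FALSE)
    if (size < 2L * binding_width + 2L) {
      stop("ring_lattice needs size >= 2 * binding_width + 2", call. = FALSE)
    }
  }
  structure(list(model = model, size = size, binding_width = binding_width),
            class = "complex_model_spec")
}

#' Generate the internal graph of one complex
#'
#' @param spec a [complex_model_spec()].
#' @param labels optional character vector of `spec$size` vertex names
#'   (defaults to `m1..msize`).
#' @return interaction network on `spec$size` vertices.
#' @export
generate_complex_graph <- function(spec, labels = NULL) {
  stopifnot(inherits(spec, "complex_model_spec"))
  n <- spec$size
  if (is.null(labels)) labels <- sprintf("m%d", seq_len(n))
  stopifnot(length(labels) == n)
  pairs <- switch(spec$model,
    clique = t(utils::combn(n, 2)),
    hub_spoke = cbind(1L, 2:n),
    ring_lattice = {
      b <- spec$binding_width
      do.call(rbind, lapply(seq_len(b), function(off) {
        cbind(seq_len(n), ((seq_len(n) - 1L + off) %% n) + 1L)
      }))
    })
  interaction_network(cbind(labels[pairs[, 1]], labels[pairs[, 2]]))
}

#' Edge-noise model for the observation layer
#'
#' Emulates an error-prone two-hybrid screen: each true edge is missed
#' (dropped) independently with probability `false_negative_rate`; spurious
#' edges are inserted as uniformly random non-adjacent vertex pairs, with
#' expected count `false_positive_rate` times the number of true edges.
#' Parameterizing false positives relative to the true edge count (rather
#' than per non-edge pair) keeps sparsity stable as networks grow.
#'
#' @param false_negative_rate probability in \[0, 1\].
#' @param false_positive_rate nonnegative rate relative to true edge count.
#' @export
noise_spec <- function(false_negative_rate = 0.1, false_positive_rate = 0.05) {
  stopifnot(false_negative_rate >= 0, false_negative_rate <= 1,
            false_positive_rate >= 0)
  structure(list(false_negative_rate = false_negative_rate,
                 false_positive_rate = false_positive_rate),
            class = "noise_spec")
}

#' Specification of a synthetic interaction study
#'
#' Bundles everything needed to emulate the real inputs of a complex survey:
#' a sparse background network with heavy-tailed degrees, a set of planted
#' complexes wired by [complex_model_spec()] models and tied to the
#' background by 1-3 random bridge edges each, and a noisy observation layer
#' ([noise_spec()]).  Defaults describe the study conditions used throughout
#' the package's own analyses: a 500-vertex power-law background (exponent
#' 2.5), 20 ring-lattice complexes with binding width 2 and sizes evenly
#' spread over 6-30, a 10% false-negative rate and a 5% false-positive rate.
#'
#' @param n_background_vertices background size.
#' @param background_model `"configuration_power_law"` or `"erdos_renyi"`.
#' @param background_params list of model parameters: `exponent` and
#'   `min_degree` for the power-law model, `p` for Erdos-Renyi.
#' @param complexes list of [complex_model_spec()]s.
#' @param noise a [noise_spec()].
#' @param seed integer seed; generation is fully deterministic given it.
#' @export
synthetic_study_spec <- function(
    n_background_vertices = 500L,
    background_model = c("configuration_power_law", "erdos_renyi"),
    background_params = list(exponent = 2.5, min_degree = 1L, p = 0.01),
    complexes = lapply(round(seq(6, 30, length.out = 20)), function(s) {
      complex_model_spec("ring_lattice", size = s, binding_width = 2L)
    }),
    noise = noise_spec(),
    seed = 1L) {
  background_model <- match.arg(background_model)
  stopifnot(inherits(noise, "noise_spec"),
            all(vapply(complexes, inherits, logical(1), "complex_model_spec")))
  structure(list(n_background_vertices = as.integer(n_background_vertices),
                 background_model = background_model,
                 background_params = background_params,
                 complexes = complexes, noise = noise,
                 seed = as.integer(seed)),
            class = "synthetic_study_spec")
}

#' Generate the background network
#'
#' `configuration_power_law` draws degrees from a discrete power law
#' (exponent `background_params$exponent`, minimum `min_degree`, capped at
#' `n - 1`), realizes them with the configuration model and erases
#' multi-edges and self-loops, giving a simple sparse graph with a
#' heavy-tailed degree sequence.  `erdos_renyi` is a G(n, p) baseline.
#'
#' @param spec a [synthetic_study_spec()].
#' @param seed optional integer; seeds the RNG for this call.
#' @return interaction network with vertices `B0001`, `B0002`, ...
#' @export
generate_background <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  n <- spec$n_background_vertices
  if (spec$background_model == "erdos_renyi") {
    g <- igraph::sample_gnp(n, spec$background_params$p)
  } else {
    alpha <- spec$background_params$exponent
    dmin <- max(1L, as.integer(spec$background_params$min_degree %||% 1L))
    # inverse-transform sample of a continuous power law, floored
    u <- stats::runif(n)
    deg <- floor(dmin * u^(-1 / (alpha - 1)))
    deg <- pmin(deg, n - 1L)
    if (sum(deg) %% 2 == 1) deg[which.min(deg)] <- deg[which.min(deg)] + 1L
    g <- igraph::simplify(igraph::sample_degseq(deg, method = "configuration"))
  }
  igraph::V(g)$name <- sprintf("B%04d", seq_len(n))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plant complexes in a background and observe with noise
#'
#' Builds the full synthetic study: generates the background, embeds each
#' complex on fresh disjoint vertex labels (`C01_01`, ...) with its model
#' edges, attaches each complex to the background by 1-3 uniformly chosen
#' bridge edges, then applies the observation layer of `spec$noise` to all
#' true edges.  Membership lists are emitted pre-noise (catalog knowledge is
#' about membership; noise lives on edges), and the truth list additionally
#' carries each complex's pre-noise internal edges as reference edges (the
#' crystallography analogue).
#'
#' @param spec a [synthetic_study_spec()].
#' @return list with `network` (observed), `complexes` (membership-only
#'   definitions), `truth` (definitions with reference edges), and
#'   `true_network` (pre-noise union graph).
#' @export
plant_and_observe <- function(spec) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  set.seed(spec$seed %% .Machine$integer.max)
  bg <- generate_background(spec)
  all_edges <- igraph::as_edgelist(bg)
  all_vertices <- igraph::V(bg)$name
  complexes <- list()
  truth <- list()
  for (ci in seq_along(spec$complexes)) {
    cspec <- spec$complexes[[ci]]
    labels <- sprintf("C%02d_%02d", ci, seq_len(cspec$size))
    cg <- generate_complex_graph(cspec, labels)
    cedges <- igraph::as_edgelist(cg)
    id <- sprintf("CPX%02d", ci)
    complexes[[ci]] <- complex_definition(id, labels)
    truth[[ci]] <- complex_definition(id, labels, reference_edges = cedges)
    n_bridge <- sample(1:3, 1L)
    bridges <- cbind(sample(labels, n_bridge, replace = TRUE),
                     sample(igraph::V(bg)$name, n_bridge, replace = FALSE))
    all_edges <- rbind(all_edges, cedges, bridges)
    all_vertices <- c(all_vertices, labels)
  }
  true_net <- interaction_network(all_edges, vertices = all_vertices)
  observed <- .observe(true_net, spec$noise)
  list(network = observed, complexes = complexes, truth = truth,
       true_network = true_net)
}

# observation layer: independent edge dropout plus spurious-pair insertion
.observe <- function(true_net, noise) {
  el <- igraph::as_edgelist(true_net)
  m <- nrow(el)
  keep <- stats::runif(m) >= noise$false_negative_rate
  kept <- el[keep, , drop = FALSE]
  verts <- igraph::V(true_net)$name
  n_fp <- stats::rpois(1, noise$false_positive_rate * m)
  fp <- matrix(character(), ncol = 2)
  if (n_fp > 0) {
    true_keys <- .edge_keys(el)
    got <- character(0)
    guard <- 0L
    while (length(got) < n_fp && guard < 50L * n_fp) {
      guard <- guard + 1L
      pair <- sample(verts, 2L)
      key <- .edge_keys(matrix(pair, ncol = 2))
      if (key %in% true_keys || key %in% got) next
      got <- c(got, key)
      fp <- rbind(fp, pair)
    }
  }
  interaction_network(rbind(kept, fp), vertices = verts)
}

#' Write a synthetic study to disk
#'
#' Emits the same plain-text formats the pipeline reads: the observed
#' network as a two-column edge list (`network.tsv`), membership lists
#' (`complexes.tsv`), reference edges (`reference.tsv`), plus a JSON
#' provenance record of the generating spec and seed (`provenance.json`).
#'
#' @param study result of [plant_and_observe()].
#' @param spec the generating [synthetic_study_spec()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(study, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(study$network, file.path(dir, "network.tsv"))
  write_complexes(study$complexes, file.path(dir, "complexes.tsv"))
  write_reference_complexes(study$truth, file.path(dir, "reference.tsv"))
  prov <- list(
    n_background_vertices = spec$n_background_vertices,
    background_model = spec$background_model,
    background_params = spec$background_params,
    complexes = lapply(spec$complexes, unclass),
    noise = unclass(spec$noise),
    seed = spec$seed)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
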