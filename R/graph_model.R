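# Double graph of transcriptional activations and repressions.

.edge_matrix <- function(x, what) {
  if (is.null(x) || (is.list(x) && length(x) == 0)) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("source", "target"))))
  }
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 2)
    m <- x
  } else if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 2)
    m <- as.matrix(x[, 1:2])
  } else if (is.list(x)) {
    if (!all(vapply(x, length, 1L) == 2))
      stop("each edge must be a pair (source, target)")
    m <- do.call(rbind, lapply(x, as.character))
  } else stop("cannot interpret ", what, " edges")
  storage.mode(m) <- "character"
  dimnames(m) <- list(NULL, c("source", "target"))
  if (any(!nzchar(m)) || any(is.na(m)))
    stop(what, " edges contain empty or missing vertex names")
  m
}

.default_annotations <- function(vertices) {
  data.frame(vertex = vertices,
             constant_input = FALSE,
             is_mrna = FALSE,
             initial = NA_real_,
             stringsAsFactors = FALSE)
}

#' Construct a regulatory double graph
#'
#' A double graph is a vertex set together with two edge sets over the same
#' vertices: ordered activation pairs and ordered repression pairs. Vertices
#' stand for genes/proteins (same symbol for both), transcription-factor
#' inputs, or mRNAs. The order of edges in the input fixes the canonical
#' regulator order used downstream for operon-state and parameter naming.
#'
#' @param vertices character vector of vertex names (may be empty; endpoints
#'   of edges are added automatically).
#' @param activations,repressions edge sets: a list of pairs, a two-column
#'   matrix, or a two-column data frame `(source, target)`.
#' @param annotations optional named list; each element is a list with any of
#'   `constant_input` (logical), `is_mrna` (logical), `initial` (non-negative
#'   numeric, concentration units).
#' @return an object of class `double_graph`.
#' @examples
#' g <- double_graph(activations = list(c("A", "B")),
#'                   repressions = list(c("R", "B")))
#' regulators_of(g, "B")
#' @export
double_graph <- function(vertices = character(), activations = NULL,
                         repressions = NULL, annotations = NULL) {
  act <- .edge_matrix(activations, "activation")
  rep_ <- .edge_matrix(repressions, "repression")
  vertices <- as.character(vertices)
  verts <- unique(c(vertices, as.vector(t(act)), as.vector(t(rep_)),
                    names(annotations)))
  if (anyNA(verts) || any(!nzchar(verts))) stop("invalid vertex names")
  ann <- .default_annotations(verts)
  rownames(ann) <- verts
  for (v in names(annotations)) {
    a <- annotations[[v]]
    if (!is.null(a$constant_input)) ann[v, "constant_input"] <- isTRUE(a$constant_input)
    if (!is.null(a$is_mrna)) ann[v, "is_mrna"] <- isTRUE(a$is_mrna)
    if (!is.null(a$initial)) {
      if (a$initial < 0) stop("initial concentration for '", v, "' is negative")
      ann[v, "initial"] <- as.numeric(a$initial)
    }
  }
  g <- structure(list(vertices = verts, activations = act,
                      repressions = rep_, annotations = ann),
                 class = "double_graph")
  validate_double_graph(g)
  g
}

#' Validate a double graph
#'
#' Checks the structural invariants: unique vertex names, edge endpoints
#' present in the vertex set, no duplicate edge within an edge set, and no
#' ordered pair present in both the activation and the repression set.
#'
#' @param g a `double_graph`.
#' @return `g`, invisibly; errors describe the offending pair.
#' @export
validate_double_graph <- function(g) {
  stopifnot(inherits(g, "double_graph"))
  if (anyDuplicated(g$vertices))
    stop("duplicate vertex names: ",
         paste(unique(g$vertices[duplicated(g$vertices)]), collapse = ", "))
  key <- function(m) paste(m[, 1], m[, 2], sep = "\r")
  for (set in c("activations", "repressions")) {
    m <- g[[set]]
    if (!all(m %in% g$vertices)) stop("edge endpoint not in vertex set")
    d <- duplicated(key(m))
    if (any(d)) stop("duplicate ", set, " edge: (",
                     m[which(d)[1], 1], ", ", m[which(d)[1], 2], ")")
  }
  both <- intersect(key(g$activations), key(g$repressions))
  if (length(both)) {
    p <- strsplit(both[1], "\r", fixed = TRUE)[[1]]
    stop("pair (", p[1], ", ", p[2],
         ") appears in both the activation and the repression set")
  }
  invisible(g)
}

#' Parse a network from activation and repression pair lists
#'
#' Thin validating constructor mirroring the two-string input convention: the
#' vertex set is the union of all edge endpoints plus annotated vertices.
#'
#' @inheritParams double_graph
#' @param activation_pairs,repression_pairs edge sets (list of pairs, matrix
#'   or data frame).
#' @return a validated `double_graph`.
#' @export
parse_network <- function(activation_pairs, repression_pairs, annotations = NULL) {
  double_graph(activations = activation_pairs, repressions = repression_pairs,
               annotations = annotations)
}

#' Incoming regulators of a gene
#'
#' Returns the activator and repressor source vertices of `gene`, each in the
#' deterministic order in which the edges were given. mRNA-flagged regulators
#' can be excluded (they model translation, not transcriptional binding).
#'
#' @param g a `double_graph`.
#' @param gene vertex name.
#' @param drop_mrna drop regulators annotated `is_mrna` (default `FALSE`).
#' @return list with components `activators` and `repressors`.
#' @export
regulators_of <- function(g, gene, drop_mrna = FALSE) {
  stopifnot(inherits(g, "double_graph"))
  if (!gene %in% g$vertices) stop("unknown vertex: '", gene, "'")
  acts <- g$activations[g$activations[, 2] == gene, 1]
  reps <- g$repressions[g$repressions[, 2] == gene, 1]
  if (drop_mrna) {
    mrna <- g$vertices[g$annotations$is_mrna]
    acts <- setdiff(acts, mrna)
    reps <- setdiff(reps, mrna)
  }
  list(activators = unname(acts), repressors = unname(reps))
}

#' Infer vertex roles from graph structure
#'
#' A vertex with incoming regulation edges represents a gene together with its
#' protein (an operon with binding states); a vertex with only outgoing edges
#' is a transcription-factor input; a vertex annotated `is_mrna` is an mRNA
#' excluded from the kinetics; an isolated vertex is treated as an
#' unregulated gene.
#'
#' @param g a `double_graph`.
#' @return named character vector with values `"gene"`, `"input"`, `"mrna"`.
#' @export
vertex_roles <- function(g) {
  stopifnot(inherits(g, "double_graph"))
  mrna <- g$vertices[g$annotations$is_mrna]
  roles <- setNames(character(length(g$vertices)), g$vertices)
  for (v in g$vertices) {
    if (v %in% mrna) { roles[v] <- "mrna"; next }
    inc <- c(g$activations[g$activations[, 2] == v, 1],
             g$repressions[g$repressions[, 2] == v, 1])
    inc <- setdiff(inc, mrna)   # translation edges do not make a vertex a gene
    out <- any(g$activations[, 1] == v) || any(g$repressions[, 1] == v)
    if (length(inc) > 0) roles[v] <- "gene"
    else if (out || g$annotations[v, "constant_input"]) roles[v] <- "input"
    else roles[v] <- "gene"     # isolated annotated vertex: unregulated gene
  }
  # explicit constant_input annotation overrides inference
  roles[g$annotations$vertex[g$annotations$constant_input]] <- "input"
  roles
}

#' @export
print.double_graph <- function(x, ...) {
  cat("double graph:", length(x$vertices), "vertices,",
      nrow(x$activations), "activations,", nrow(x$repressions), "repressions\n")
  cat("  V =", paste(x$vertices, collapse = ", "), "\n")
  if (nrow(x$activations))
    cat("  A:", paste(sprintf("%s -> %s", x$activations[, 1],
                              x$activations[, 2]), collapse = "; "), "\n")
  if (nrow(x$repressions))
    cat("  I:", paste(sprintf("%s -| %s", x$repressions[, 1],
                              x$repressions[, 2]), collapse = "; "), "\n")
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

.ann_to_list <- function(ann) {
  out <- list()
  for (i in seq_len(nrow(ann))) {
    a <- list()
    if (ann$constant_input[i]) a$constant_input <- TRUE
    if (ann$is_mrna[i]) a$is_mrna <- TRUE
    if (!is.na(ann$initial[i])) a$initial <- ann$initial[i]
    if (length(a)) out[[ann$vertex[i]]] <- a
  }
  out
}

#' Read/write a network as JSON
#'
#' The JSON document has keys `"vertices"`, `"activations"`, `"repressions"`
#' (arrays of `[source, target]` pairs) and `"annotations"`.
#'
#' @param g a `double_graph`.
#' @param path file path.
#' @return `read_network_json` returns a `double_graph`; the writer returns
#'   `path` invisibly.
#' @export
write_network_json <- function(g, path) {
  stopifnot(inherits(g, "double_graph"))
  obj <- list(
    vertices = g$vertices,
    activations = unname(apply(g$activations, 1, as.list, simplify = FALSE)),
    repressions = unname(apply(g$repressions, 1, as.list, simplify = FALSE)),
    annotations = .ann_to_list(g$annotations)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  to_pairs <- function(x) lapply(x, function(p) c(p[[1]], p[[2]]))
  double_graph(vertices = unlist(obj$vertices),
               activations = to_pairs(obj$activations),
               repressions = to_pairs(obj$repressions),
               annotations = obj$annotations)
}

#' Read/write a network as two edge-list CSV files
#'
#' Each CSV has columns `source,target`; activation and repression edges live
#' in separate files.
#'
#' @param g a `double_graph`.
#' @param activations_path,repressions_path file paths.
#' @param annotations optional annotations for the reader.
#' @export
write_network_csv <- function(g, activations_path, repressions_path) {
  stopifnot(inherits(g, "double_graph"))
  write.csv(as.data.frame(g$activations), activations_path, row.names = FALSE)
  write.csv(as.data.frame(g$repressions), repressions_path, row.names = FALSE)
  invisible(c(activations_path, repressions_path))
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(activations_path, repressions_path,
                             annotations = NULL) {
  act <- read.csv(activations_path, stringsAsFactors = FALSE,
                  colClasses = "character")
  rep_ <- read.csv(repressions_path, stringsAsFactors = FALSE,
                   colClasses = "character")
  double_graph(activations = act, repressions = rep_,
               annotations = annotations)
}

#' Convert a double graph to an igraph object
#'
#' Edges carry a `type` attribute (`"activation"` or `"repression"`), which
#' survives GraphML/DOT export.
#'
#' @param g a `double_graph`.
#' @return an `igraph` directed graph.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "double_graph"))
  edges <- rbind(g$activations, g$repressions)
  types <- c(rep("activation", nrow(g$activations)),
             rep("repression", nrow(g$repressions)))
  ig <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], type = types,
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = g$vertices, stringsAsFactors = FALSE))
  ig
}

#' Export a double graph for visualization
#'
#' @param g a `double_graph`.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @export
export_graph <- function(g, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(as_igraph(g), path, format = format)
  invisible(path)
}
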