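#' Multilayer chaperone-client interaction network
#'
#' A `cci_network` holds L aligned binary bipartite layers over shared node
#' sets: a small set of chaperones (rows) and a large set of clients
#' (columns), with one layer per environment (e.g. one cancer type). It is
#' stored as a tidy edge table plus the full node and layer universes, so
#' nodes with no links in a layer (or anywhere) are retained.
#'
#' @param edges data frame with columns `chaperone`, `client`, `layer`
#'   (character or coercible); one row per interaction.
#' @param chaperones,clients optional character vectors giving the complete
#'   node sets. Defaults to the identifiers seen in `edges`, sorted
#'   lexicographically (C collation) for reproducible ordering.
#' @param layers optional character vector fixing layer order. Defaults to the
#'   sorted set of layers seen in `edges`.
#'
#' @return An object of class `cci_network`: a list with elements `edges`
#'   (tibble), `chaperones`, `clients`, `layers`.
#' @examples
#' net <- cci_network(data.frame(
#'   chaperone = c("h1", "h1"), client = c("p1", "p2"),
#'   layer = c("A", "B")
#' ))
#' layer_matrices(net)
#' @export
cci_network <- function(edges, chaperones = NULL, clients = NULL, layers = NULL) {
  stopifnot(is.data.frame(edges))
  need <- c("chaperone", "client", "layer")
  if (!all(need %in% names(edges))) {
    stop("`edges` must have columns chaperone, client, layer", call. = FALSE)
  }
  edges <- tibble::as_tibble(edges[need])
  edges$chaperone <- as.character(edges$chaperone)
  edges$client <- as.character(edges$client)
  edges$layer <- as.character(edges$layer)

  dup <- duplicated(edges)
  if (any(dup)) {
    warning(sum(dup), " duplicated edge row(s) removed", call. = FALSE)
    edges <- edges[!dup, , drop = FALSE]
  }

  chaperones <- if (is.null(chaperones)) sort_ids(unique(edges$chaperone)) else as.character(chaperones)
  clients <- if (is.null(clients)) sort_ids(unique(edges$client)) else as.character(clients)
  layers <- if (is.null(layers)) sort_ids(unique(edges$layer)) else as.character(layers)

  if (anyDuplicated(chaperones)) stop("duplicated chaperone identifiers", call. = FALSE)
  if (anyDuplicated(clients)) stop("duplicated client identifiers", call. = FALSE)
  if (anyDuplicated(layers)) stop("duplicated layer identifiers", call. = FALSE)
  if (length(intersect(chaperones, clients))) {
    stop("chaperone and client identifier sets overlap", call. = FALSE)
  }

  bad <- !(edges$chaperone %in% chaperones) | !(edges$client %in% clients) |
    !(edges$layer %in% layers)
  if (any(bad)) stop("edges reference unknown nodes or layers", call. = FALSE)

  structure(
    list(edges = edges, chaperones = chaperones, clients = clients, layers = layers),
    class = "cci_network"
  )
}

# locale-independent lexicographic sort
sort_ids <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  sort(x)
}

#' Coerce to a multilayer CCI network
#'
#' @param x a `cci_network`, an edge data frame (columns `chaperone`,
#'   `client`, `layer`), or a named list of binary incidence matrices with
#'   identical dimnames (chaperones in rows, clients in columns).
#' @param ... passed to [cci_network()].
#' @return a `cci_network`.
#' @export
as_cci_network <- function(x, ...) UseMethod("as_cci_network")

#' @export
as_cci_network.cci_network <- function(x, ...) x

#' @export
as_cci_network.data.frame <- function(x, ...) cci_network(x, ...)

#' @export
as_cci_network.list <- function(x, ...) {
  stopifnot(length(x) >= 1, !is.null(names(x)))
  ref <- x[[1]]
  if (is.null(rownames(ref)) || is.null(colnames(ref))) {
    stop("incidence matrices must carry dimnames", call. = FALSE)
  }
  edges <- purrr::map2_dfr(x, names(x), function(m, id) {
    idx <- which(m != 0, arr.ind = TRUE)
    tibble::tibble(
      chaperone = rownames(m)[idx[, 1]],
      client = colnames(m)[idx[, 2]],
      layer = id
    )
  })
  cci_network(edges,
    chaperones = rownames(ref), clients = colnames(ref),
    layers = names(x), ...
  )
}

#' @export
print.cci_network <- function(x, ...) {
  cat(
    "<cci_network> ", length(x$chaperones), " chaperones x ",
    length(x$clients), " clients x ", length(x$layers), " layers, ",
    nrow(x$edges), " edges\n",
    sep = ""
  )
  invisible(x)
}

#' Per-layer binary incidence matrices
#'
#' @param net a [cci_network()] (or anything [as_cci_network()] accepts).
#' @return named list (one element per layer, in layer order) of 0/1 matrices,
#'   chaperones in rows and clients in columns, shared dimnames across layers.
#' @export
layer_matrices <- function(net) {
  net <- as_cci_network(net)
  template <- matrix(
    0L, length(net$chaperones), length(net$clients),
    dimnames = list(net$chaperones, net$clients)
  )
  out <- lapply(net$layers, function(a) {
    m <- template
    e <- net$edges[net$edges$layer == a, , drop = FALSE]
    if (nrow(e)) m[cbind(e$chaperone, e$client)] <- 1L
    m
  })
  names(out) <- net$layers
  out
}

#' Read a multilayer network from per-layer edge-list files
#'
#' Each layer is a UTF-8 tab-separated file with header `chaperone<TAB>client`
#' and one interaction per row. A YAML manifest fixes layer order (and
#' optionally the full node sets, so isolated nodes survive a round trip):
#'
#' ```yaml
#' layers:
#'   - BRCA: brca.tsv
#'   - LUAD: luad.tsv
#' chaperones: [h1, h2]   # optional
#' clients: [p1, p2, p3]  # optional
#' ```
#'
#' Node sets default to the union of identifiers across all files, ordered
#' lexicographically. Duplicate edge rows are deduplicated with a warning; an
#' empty file is a valid all-zero layer (warning); a row without exactly two
#' fields is an error naming the file and line.
#'
#' @param directory_path directory containing the manifest and edge lists.
#' @param manifest manifest file name within `directory_path` (default
#'   `"manifest.yml"`), or an already-parsed manifest list.
#' @return a [cci_network()].
#' @export
read_network_layers <- function(directory_path, manifest = "manifest.yml") {
  if (is.character(manifest)) {
    manifest <- yaml::read_yaml(file.path(directory_path, manifest))
  }
  stopifnot(is.list(manifest), !is.null(manifest$layers))
  entries <- manifest$layers
  layer_ids <- vapply(entries, function(e) names(e)[1], character(1))
  files <- vapply(entries, function(e) as.character(e[[1]]), character(1))

  edge_tabs <- purrr::map2(files, layer_ids, function(f, id) {
    path <- file.path(directory_path, f)
    if (!file.exists(path)) stop("missing layer file: ", path, call. = FALSE)
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (length(lines) <= 1) {
      warning("layer '", id, "' has no edges (all-zero layer)", call. = FALSE)
      return(tibble::tibble(
        chaperone = character(), client = character(),
        layer = character()
      ))
    }
    body <- lines[-1]
    parts <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 2)) {
      bad <- which(nf != 2)[1]
      stop(
        "malformed row in ", path, " at line ", bad + 1L,
        " (expected 2 tab-separated fields)",
        call. = FALSE
      )
    }
    tibble::tibble(
      chaperone = vapply(parts, `[[`, character(1), 1),
      client = vapply(parts, `[[`, character(1), 2),
      layer = id
    )
  })
  edges <- dplyr::bind_rows(edge_tabs)

  cci_network(
    edges,
    chaperones = if (!is.null(manifest$chaperones)) {
      as.character(manifest$chaperones)
    } else {
      sort_ids(unique(edges$chaperone))
    },
    clients = if (!is.null(manifest$clients)) {
      as.character(manifest$clients)
    } else {
      sort_ids(unique(edges$client))
    },
    layers = layer_ids
  )
}

#' Write a multilayer network as per-layer edge lists plus manifest
#'
#' Inverse of [read_network_layers()]: `read(write(net))` reproduces `net`
#' exactly, including isolated nodes (node sets are recorded in the manifest).
#'
#' @param net a [cci_network()].
#' @param directory_path output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_network_layers <- function(net, directory_path) {
  net <- as_cci_network(net)
  ok <- dir.exists(directory_path) || dir.create(directory_path, recursive = TRUE)
  if (!ok) stop("cannot create directory: ", directory_path, call. = FALSE)

  files <- paste0("layer_", gsub("[^A-Za-z0-9_.-]", "_", net$layers), ".tsv")
  for (i in seq_along(net$layers)) {
    e <- net$edges[net$edges$layer == net$layers[i], c("chaperone", "client")]
    e <- e[order(e$chaperone, e$client, method = "radix"), , drop = FALSE]
    path <- file.path(directory_path, files[i])
    con <- file(path, open = "wb")
    writeLines(
      c("chaperone\tclient", paste(e$chaperone, e$client, sep = "\t")),
      con
    )
    close(con)
  }
  manifest <- list(
    layers = purrr::map2(net$layers, files, function(id, f) stats::setNames(list(f), id)),
    chaperones = as.list(net$chaperones),
    clients = as.list(net$clients)
  )
  mpath <- file.path(directory_path, "manifest.yml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' Validate a multilayer network representation
#'
#' Checks the invariants a multilayer CCI network must satisfy: binary
#' entries, identical row/column orderings across layers, and no duplicated
#' identifiers. Accepts either a `cci_network` or a raw named list of
#' incidence matrices (the form in which alignment or binarity can actually
#' be violated).
#'
#' @param net a `cci_network` or named list of matrices.
#' @return tibble with columns `check`, `ok`, `detail`; zero rows with
#'   `ok = FALSE` means the network is valid. Only violated checks carry
#'   detail text.
#' @export
validate_multilayer <- function(net) {
  issues <- list()
  add <- function(check, detail) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      check = check, ok = FALSE, detail = detail
    )
  }

  if (inherits(net, "cci_network")) {
    if (anyDuplicated(net$chaperones)) add("unique_chaperones", "duplicated chaperone ids")
    if (anyDuplicated(net$clients)) add("unique_clients", "duplicated client ids")
    if (anyDuplicated(net$layers)) add("unique_layers", "duplicated layer ids")
    if (anyDuplicated(net$edges)) add("unique_edges", "duplicated edge rows")
    unknown <- !(net$edges$chaperone %in% net$chaperones) |
      !(net$edges$client %in% net$clients) |
      !(net$edges$layer %in% net$layers)
    if (any(unknown)) add("known_nodes", paste(sum(unknown), "edges reference unknown ids"))
  } else if (is.list(net)) {
    ref <- net[[1]]
    for (i in seq_along(net)) {
      m <- net[[i]]
      id <- names(net)[i] %||% as.character(i)
      if (!all(m %in% c(0, 1))) {
        add("binary_entries", paste0("layer '", id, "' has non-binary entries"))
      }
      if (!identical(dimnames(m), dimnames(ref))) {
        add("aligned_layers", paste0("layer '", id, "' row/column ordering differs from first layer"))
      }
    }
    if (!is.null(rownames(ref)) && anyDuplicated(rownames(ref))) {
      add("unique_chaperones", "duplicated row ids")
    }
    if (!is.null(colnames(ref)) && anyDuplicated(colnames(ref))) {
      add("unique_clients", "duplicated column ids")
    }
  } else {
    stop("unsupported network representation", call. = FALSE)
  }

  if (length(issues)) dplyr::bind_rows(issues) else {
    tibble::tibble(check = character(), ok = logical(), detail = character())
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
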