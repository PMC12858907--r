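#' Read a metabolite class map
#'
#' TSV with columns \code{metabolite_id} and \code{class}; classes are
#' one of amino_acid, organic_acid, carbohydrate, vitamin, nucleotide,
#' other. Metabolites absent from the map default to \code{other}. With no
#' path, the table shipped with the package (covering commonly exchanged
#' amino acids, organic acids, vitamins, sugars and nucleotides) is used.
#'
#' @param path TSV path, or NULL for the packaged default.
#' @return object of class \code{class_map}.
#' @export
read_class_map <- function(path = NULL) {
  src <- if (is.null(path))
    system.file("extdata", "metabolite_classes.tsv", package = "commfba")
  else path
  df <- utils::read.table(src, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("metabolite_id", "class") %in% names(df)))
    stop("class map needs columns metabolite_id, class: ", src)
  if (anyDuplicated(df$metabolite_id))
    stop("metabolite mapped to more than one class: ",
         df$metabolite_id[duplicated(df$metabolite_id)][1L])
  structure(list(classes = stats::setNames(df$class, df$metabolite_id),
                 source = src),
            class = "class_map")
}

metabolite_class <- function(class_map, met) {
  if (is.null(class_map)) return(rep("other", length(met)))
  cl <- unname(class_map$classes[met])
  cl[is.na(cl)] <- "other"
  cl
}

#' Extract the cross-feeding network from a community solution
#'
#' For every pool metabolite with at least one secreting strain (exchange
#' flux > epsilon) and one consuming strain (< -epsilon), directed
#' donor -> recipient edges are created. With multiple donors and/or
#' recipients the recipient's uptake is allocated proportionally to donor
#' secretion magnitudes; medium import (IP) counts as unattributed supply,
#' never as a donor, so for every metabolite the edge allocations plus the
#' unattributed import equal the total uptake.
#'
#' @param solution an optimal \code{community_solution} (pFBA solutions
#'   recommended, to suppress alternate-optimum exchanges).
#' @param class_map a \code{\link{read_class_map}} result, or NULL for all
#'   classes \code{other}.
#' @param epsilon flux threshold for calling an exchange (default 1e-6).
#' @return object of class \code{crossfeeding_network}: \code{nodes},
#'   \code{edges} (data.frame: metabolite, class, donor, recipient,
#'   donor_flux, recipient_flux, allocated_flux, unattributed per
#'   recipient), \code{per_class_counts}, \code{unidirectional_donors}.
#' @export
extract_cross_feeding <- function(solution, class_map = NULL,
                                  epsilon = EPS_FLUX) {
  if (!inherits(solution, "community_solution"))
    stop("need a community_solution")
  if (solution$status != "optimal")
    stop("cross-feeding requires an optimal solution, got status ",
         solution$status)
  nodes <- names(solution$strain_biomass)
  edges <- list()
  for (m in names(solution$pool_flows)) {
    pf <- solution$pool_flows[[m]]
    per <- pf$per_strain
    donors <- per[per > epsilon]
    takers <- -per[per < -epsilon]
    if (!length(donors) || !length(takers)) next
    supply <- sum(donors) + max(pf$IP, 0)
    cl <- metabolite_class(class_map, m)
    for (r in names(takers)) {
      for (d in names(donors)) {
        if (d == r) next
        edges[[length(edges) + 1L]] <- data.frame(
          metabolite = m, class = cl, donor = d, recipient = r,
          donor_flux = unname(donors[d]), recipient_flux = unname(takers[r]),
          allocated_flux = unname(takers[r] * donors[d] / supply))
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(metabolite = character(), class = character(),
               donor = character(), recipient = character(),
               donor_flux = numeric(), recipient_flux = numeric(),
               allocated_flux = numeric())
  new_crossfeeding_network(nodes, edges)
}

new_crossfeeding_network <- function(nodes, edges) {
  pcc <- if (nrow(edges)) {
    agg <- stats::aggregate(metabolite ~ donor + recipient + class,
                            data = unique(edges[, c("metabolite", "class",
                                                    "donor", "recipient")]),
                            FUN = length)
    names(agg)[names(agg) == "metabolite"] <- "n_metabolites"
    agg[order(agg$donor, agg$recipient, agg$class), , drop = FALSE]
  } else {
    data.frame(donor = character(), recipient = character(),
               class = character(), n_metabolites = integer())
  }
  rownames(pcc) <- NULL
  is_donor <- nodes %in% edges$donor
  is_recip <- nodes %in% edges$recipient
  structure(list(nodes = nodes, edges = edges, per_class_counts = pcc,
                 unidirectional_donors = nodes[is_donor & !is_recip]),
            class = "crossfeeding_network")
}

#' @export
print.crossfeeding_network <- function(x, ...) {
  cat("Cross-feeding network: ", length(x$nodes), " strains, ",
      nrow(x$edges), " directed metabolite edges",
      if (length(x$unidirectional_donors))
        paste0("; unidirectional donors: ",
               paste(x$unidirectional_donors, collapse = ", ")) else "",
      "\n", sep = "")
  invisible(x)
}

#' Summarize a cross-feeding network
#'
#' Per strain: metabolite types donated (out-degree), received (in-degree)
#' and a net-donor flag; per class: number of exchanged types; community
#' totals; plus the strains with the potentiator signature -- donors that
#' receive nothing.
#'
#' @param network a \code{crossfeeding_network}.
#' @return list with \code{per_strain}, \code{per_class},
#'   \code{n_exchanged_types}, \code{potentiator_candidates}.
#' @export
network_summary <- function(network) {
  e <- network$edges
  per_strain <- do.call(rbind, lapply(network$nodes, function(k) {
    outd <- length(unique(e$metabolite[e$donor == k]))
    ind <- length(unique(e$metabolite[e$recipient == k]))
    data.frame(strain = k, out_degree = outd, in_degree = ind,
               net_donor = outd > ind,
               unidirectional_donor = outd > 0 & ind == 0)
  }))
  per_class <- if (nrow(e)) {
    u <- unique(e[, c("metabolite", "class")])
    as.data.frame(table(class = u$class), responseName = "n_types",
                  stringsAsFactors = FALSE)
  } else data.frame(class = character(), n_types = integer())
  list(per_strain = per_strain, per_class = per_class,
       n_exchanged_types = length(unique(e$metabolite)),
       potentiator_candidates =
         per_strain$strain[per_strain$unidirectional_donor])
}

#' Compare cross-feeding networks across conditions
#'
#' Tabulates, per (donor, recipient, class), the number of exchanged
#' metabolite types under each condition and their pairwise differences,
#' and lists the metabolites unique to each condition.
#'
#' @param networks named list (condition label -> crossfeeding_network)
#'   over the same strain set; >= 2 entries.
#' @return list with \code{counts} (wide data.frame, one count column per
#'   condition), \code{unique_metabolites} (per condition).
#' @export
compare_conditions <- function(networks) {
  if (length(networks) < 2) stop("need at least two conditions")
  labs <- names(networks)
  base_nodes <- sort(networks[[1]]$nodes)
  for (nw in networks)
    if (!identical(sort(nw$nodes), base_nodes))
      stop("networks span different strain sets")
  keys <- unique(do.call(rbind, lapply(networks, function(nw)
    nw$per_class_counts[, c("donor", "recipient", "class")])))
  keys <- keys[order(keys$donor, keys$recipient, keys$class), , drop = FALSE]
  rownames(keys) <- NULL
  counts <- keys
  for (lab in labs) {
    pcc <- networks[[lab]]$per_class_counts
    idx <- match(paste(keys$donor, keys$recipient, keys$class),
                 paste(pcc$donor, pcc$recipient, pcc$class))
    counts[[paste0("n_", lab)]] <- ifelse(is.na(idx), 0L, pcc$n_metabolites[idx])
  }
  if (length(labs) == 2)
    counts$difference <- counts[[paste0("n_", labs[1])]] -
      counts[[paste0("n_", labs[2])]]
  mets <- lapply(networks, function(nw) unique(nw$edges$metabolite))
  uniq <- lapply(labs, function(lab)
    setdiff(mets[[lab]], unlist(mets[setdiff(labs, lab)])))
  names(uniq) <- labs
  list(counts = counts, unique_metabolites = uniq)
}

#' Export a cross-feeding network
#'
#' GraphML (via igraph) with node attribute \code{strain_id} and edge
#' attributes metabolite, class and allocated_flux, or a plain edge-list
#' TSV with the same columns. Both round-trip through
#' \code{\link{import_network}}.
#'
#' @param network a \code{crossfeeding_network}.
#' @param path output file.
#' @param format \code{"graphml"} or \code{"edge_tsv"}.
#' @return \code{path}, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(network$nodes),
                            name = network$nodes,
                            strain_id = network$nodes)
  if (nrow(network$edges))
    g <- igraph::add_edges(
      g, rbind(network$edges$donor, network$edges$recipient),
      metabolite = network$edges$metabolite,
      class = network$edges$class,
      donor_flux = network$edges$donor_flux,
      recipient_flux = network$edges$recipient_flux,
      allocated_flux = network$edges$allocated_flux)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Re-import an exported cross-feeding network
#'
#' @param path file written by \code{\link{export_network}}.
#' @param format \code{"graphml"} or \code{"edge_tsv"}.
#' @param nodes strain ids (required for edge_tsv when some strains have no
#'   edges; ignored for graphml).
#' @return a \code{crossfeeding_network}.
#' @export
import_network <- function(path, format = c("graphml", "edge_tsv"),
                           nodes = NULL) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    e <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(metabolite = "character",
                                          class = "character",
                                          donor = "character",
                                          recipient = "character"))
    if (is.null(nodes)) nodes <- sort(unique(c(e$donor, e$recipient)))
    return(new_crossfeeding_network(nodes, e))
  }
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::vertex_attr(g, "strain_id")
  el <- igraph::as_edgelist(g, names = FALSE)
  e <- data.frame(metabolite = igraph::edge_attr(g, "metabolite"),
                  class = igraph::edge_attr(g, "class"),
                  donor = nodes[el[, 1]], recipient = nodes[el[, 2]],
                  donor_flux = igraph::edge_attr(g, "donor_flux"),
                  recipient_flux = igraph::edge_attr(g, "recipient_flux"),
                  allocated_flux = igraph::edge_attr(g, "allocated_flux"))
  if (!nrow(e))
    e <- data.frame(metabolite = character(), class = character(),
                    donor = character(), recipient = character(),
                    donor_flux = numeric(), recipient_flux = numeric(),
                    allocated_flux = numeric())
  new_crossfeeding_network(nodes, e)
}
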