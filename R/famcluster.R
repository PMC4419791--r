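# Ortholog-group clustering: an exhaustive all-vs-all protein similarity
# graph (a desk-scale stand-in for a BLASTP search -- the Markov clustering
# consumes the graph, not the search heuristic), Markov Cluster (MCL)
# iteration on the column-stochastic transition matrix, and the family-size
# classes used throughout the family statistics.

#' All-vs-all protein similarity graph
#'
#' Globally aligns every pair of proteins (within and between species) with
#' Needleman-Wunsch/BLOSUM62 and keeps an edge when fractional identity
#' over the ungapped aligned columns reaches `min_identity` and those
#' columns cover at least `min_coverage` of the longer sequence. Edge
#' weight is the identity.
#'
#' @param proteins_a,proteins_b Named character vectors of protein
#'   sequences for species A and B.
#' @param min_identity Minimum identity to keep an edge.
#' @param min_coverage Minimum aligned-column coverage of the longer
#'   sequence.
#' @param gap_open,gap_extend Affine gap penalties.
#' @param word_size,min_shared_words Candidate pairs must share at least
#'   `min_shared_words` distinct amino-acid words of length `word_size`
#'   before being aligned (the word-matching seed step of a similarity
#'   search; unrelated random proteins almost never qualify). Set
#'   `min_shared_words = 0` to align every pair exhaustively.
#' @return A list of class `similarity_graph` with `nodes` (data frame
#'   `gene`, `species`) and `edges` (data frame `from`, `to`, `weight`,
#'   symmetric by construction, stored once per unordered pair).
#' @export
similarity_graph <- function(proteins_a, proteins_b, min_identity = 0.4,
                             min_coverage = 0.5, gap_open = 10, gap_extend = 0.5,
                             word_size = 4L, min_shared_words = 5L) {
  stopifnot(!is.null(names(proteins_a)), !is.null(names(proteins_b)))
  all_prot <- c(proteins_a, proteins_b)
  species <- c(rep("A", length(proteins_a)), rep("B", length(proteins_b)))
  n <- length(all_prot)
  if (anyDuplicated(names(all_prot))) stop("gene ids must be unique across species")
  aa <- Biostrings::AAStringSet(all_prot)
  lens <- nchar(all_prot)

  # candidate pairs by shared words
  cand <- matrix(integer(0), 0, 2)
  if (min_shared_words > 0L && n > 1L) {
    words <- lapply(all_prot, function(p) {
      if (nchar(p) < word_size) return(character(0))
      unique(substring(p, 1:(nchar(p) - word_size + 1L), word_size:nchar(p)))
    })
    idx <- split(rep(seq_len(n), lengths(words)), unlist(words, use.names = FALSE))
    pair_counts <- new.env(hash = TRUE)
    for (members in idx) {
      if (length(members) < 2L) next
      for (u in seq_len(length(members) - 1L)) for (v in seq.int(u + 1L, length(members))) {
        key <- paste0(members[u], "_", members[v])
        pair_counts[[key]] <- (if (is.null(pair_counts[[key]])) 0L else pair_counts[[key]]) + 1L
      }
    }
    keys <- ls(pair_counts)
    hits <- keys[vapply(keys, function(k) pair_counts[[k]] >= min_shared_words, TRUE)]
    if (length(hits) > 0) {
      cand <- do.call(rbind, lapply(strsplit(hits, "_"), as.integer))
    }
  } else if (n > 1L) {
    cand <- t(utils::combn(n, 2L))
  }

  from <- character(0); to <- character(0); wt <- numeric(0)
  if (nrow(cand) > 0) {
    # equal-length pairs whose ungapped identity already clears the
    # threshold are accepted on the trivial diagonal alignment; only the
    # remainder needs the dynamic program
    quick <- logical(nrow(cand))
    ints <- lapply(all_prot, utf8ToInt)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1L]; j <- cand[r, 2L]
      if (lens[i] == lens[j]) {
        ident <- mean(ints[[i]] == ints[[j]])
        if (ident >= min_identity) {
          quick[r] <- TRUE
          from <- c(from, names(all_prot)[j])
          to <- c(to, names(all_prot)[i])
          wt <- c(wt, ident)
        }
      }
    }
    cand <- cand[!quick, , drop = FALSE]
  }
  if (nrow(cand) > 0) {
    for (i in unique(cand[, 1L])) {
      js <- cand[cand[, 1L] == i, 2L]
      alns <- Biostrings::pairwiseAlignment(
        aa[js], aa[[i]], substitutionMatrix = "BLOSUM62",
        gapOpening = gap_open, gapExtension = gap_extend, type = "global")
      pat <- as.character(Biostrings::alignedPattern(alns))
      sub <- as.character(Biostrings::alignedSubject(alns))
      for (k in seq_along(js)) {
        sa <- strsplit(pat[k], "")[[1]]; sb <- strsplit(sub[k], "")[[1]]
        both <- sa != "-" & sb != "-"
        if (!any(both)) next
        ident <- mean(sa[both] == sb[both])
        cov <- sum(both) / max(lens[i], lens[js[k]])
        if (ident >= min_identity && cov >= min_coverage) {
          from <- c(from, names(all_prot)[js[k]])
          to <- c(to, names(all_prot)[i])
          wt <- c(wt, ident)
        }
      }
    }
  }
  structure(list(
    nodes = data.frame(gene = names(all_prot), species = species,
                       stringsAsFactors = FALSE),
    edges = data.frame(from = from, to = to, weight = wt,
                       stringsAsFactors = FALSE)),
    class = "similarity_graph")
}

# connected components of a symmetric adjacency support (logical matrix)
.components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Markov clustering of a similarity graph
#'
#' Standard MCL: build a column-stochastic transition matrix with
#' self-loops (weight equal to the node's maximum incident weight, the
#' usual regularization), then alternate expansion (matrix squaring) and
#' inflation (entrywise power then column renormalization) until the
#' largest entry change falls below `tol` or `max_iter` is reached.
#' Clusters are the connected components of the limit matrix's support.
#' Genes in no multi-gene cluster are reported as unclustered.
#'
#' @param graph A `similarity_graph`, or a data frame of edges
#'   (`from`, `to`, `weight`).
#' @param inflation Inflation exponent (> 1).
#' @param max_iter Maximum iterations.
#' @param tol Convergence tolerance on the max entry change.
#' @param prune Entries below this value are zeroed each iteration.
#' @param species Optional named vector gene -> species tag; taken from
#'   `graph$nodes` when available, otherwise parsed as `NA`.
#' @return A list of class `mcl_clustering` with `membership` (named
#'   integer vector; 0 = unclustered singleton), `groups` (data frame
#'   `family`, `gene`, `species`), `families` (data frame `family`,
#'   `size`, `n_a`, `n_b`, `size_class`), `unclustered` (gene ids) and
#'   `converged`.
#' @export
mcl <- function(graph, inflation = 1.5, max_iter = 100L, tol = 1e-6,
                prune = 1e-8, species = NULL) {
  if (inherits(graph, "similarity_graph")) {
    edges <- graph$edges
    nodes <- graph$nodes$gene
    species <- stats::setNames(graph$nodes$species, nodes)
  } else {
    edges <- as.data.frame(graph)
    nodes <- unique(c(edges$from, edges$to))
    if (is.null(species)) species <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  }
  stopifnot(inflation > 1, length(nodes) > 0)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) {
    ei <- match(edges$from, nodes); ej <- match(edges$to, nodes)
    if (any(edges$weight <= 0)) stop("edge weights must be positive")
    A[cbind(ei, ej)] <- pmax(A[cbind(ei, ej)], edges$weight)
    A[cbind(ej, ei)] <- pmax(A[cbind(ej, ei)], edges$weight)
  }
  loop <- apply(A, 1L, max)
  diag(A) <- ifelse(loop > 0, loop, 1)
  M <- sweep(A, 2L, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M            # expansion
    M2 <- M2^inflation       # inflation
    M2[M2 < prune] <- 0
    M2 <- sweep(M2, 2L, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("MCL did not converge within max_iter; clustering the current state")
  support <- (M > prune) | t(M > prune)
  comp <- .components(support)
  sizes <- tabulate(comp)
  membership <- ifelse(sizes[comp] > 1L, comp, 0L)
  # renumber multi-gene clusters consecutively by first appearance
  relabel <- match(membership[membership > 0L], unique(membership[membership > 0L]))
  membership[membership > 0L] <- relabel
  names(membership) <- nodes
  clustered <- membership > 0L
  groups <- data.frame(family = sprintf("OG%04d", membership[clustered]),
                       gene = nodes[clustered],
                       species = unname(species[nodes[clustered]]),
                       stringsAsFactors = FALSE)
  groups <- groups[order(groups$family, groups$gene), , drop = FALSE]
  fams <- if (nrow(groups) > 0) {
    agg <- lapply(split(groups, groups$family), function(d) {
      data.frame(family = d$family[1], size = nrow(d),
                 n_a = sum(d$species %in% "A"), n_b = sum(d$species %in% "B"),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, agg)
    # species tags may be absent (plain edge-list input); then classify by
    # total size only and single-copy status is indeterminable
    out$size_class <- mapply(function(na, nb, sz) {
      if (na + nb == sz) classify_family_size(na, nb) else classify_family_size(sz, 0L)
    }, out$n_a, out$n_b, out$size)
    rownames(out) <- NULL
    out
  } else {
    data.frame(family = character(0), size = integer(0), n_a = integer(0),
               n_b = integer(0), size_class = character(0))
  }
  structure(list(membership = membership, groups = groups, families = fams,
                 unclustered = nodes[!clustered], converged = converged),
            class = "mcl_clustering")
}

#' Family-size class of an ortholog group
#'
#' Single-copy means exactly one gene from each species; otherwise the
#' total size falls into half-open bins \[2,5), \[5,10), \[10,20),
#' \[20,100), \[100, Inf). A lone gene is labelled "singleton".
#'
#' @param n_a,n_b Gene counts per species (either may be 0 for
#'   lineage-specific families).
#' @return Character size-class label.
#' @export
classify_family_size <- function(n_a, n_b) {
  size <- n_a + n_b
  if (size < 1L) stop("empty family")
  if (n_a == 1L && n_b == 1L) return("single-copy")
  if (size == 1L) return("singleton")
  if (size < 5L) "2-5" else if (size < 10L) "5-10" else if (size < 20L) "10-20"
  else if (size < 100L) "20-100" else ">100"
}

#' Ordered family-size class labels
#'
#' @return Character vector of the size classes from single-copy to >100.
#' @export
family_size_levels <- function() c("single-copy", "2-5", "5-10", "10-20", "20-100", ">100")

#' Extract single-copy ortholog pairs
#'
#' @param clustering An `mcl_clustering`, or a `groups`-like data frame
#'   with columns `family`, `gene`, `species`.
#' @return Data frame `family`, `gene_a`, `gene_b`, one row per
#'   single-copy family (exactly one gene in each species).
#' @export
single_copy_pairs <- function(clustering) {
  groups <- if (inherits(clustering, "mcl_clustering")) clustering$groups else clustering
  out <- lapply(split(groups, groups$family), function(d) {
    a <- d$gene[d$species == "A"]; b <- d$gene[d$species == "B"]
    if (length(a) == 1L && length(b) == 1L && nrow(d) == 2L) {
      data.frame(family = d$family[1], gene_a = a, gene_b = b,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(family = character(0), gene_a = character(0),
                      gene_b = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
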