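#' Newick I/O with validation
#'
#' Thin wrappers around the `ape` Newick parser that enforce the package's
#' tree contract: unique tip labels and branch lengths present.
#'
#' @param path file path.
#' @param tree an `ape::phylo` object (for writing).
#' @return `read_newick`: a `phylo`; `write_newick`: `path` invisibly.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("parse error: not a valid Newick file: ", path, call. = FALSE)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  validate_phylogeny(tree)
  tree
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  validate_phylogeny(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Validate a phylogeny against the package contract
#' @param tree an `ape::phylo`.
#' @param require_lengths require branch lengths (default TRUE).
#' @return `tree`, invisibly.
#' @export
validate_phylogeny <- function(tree, require_lengths = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (ape::Ntip(tree) < 2L) stop("tree needs at least 2 tips", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("input error: duplicate tip labels", call. = FALSE)
  }
  if (require_lengths) {
    if (is.null(tree$edge.length)) stop("tree lacks branch lengths", call. = FALSE)
    if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  }
  invisible(tree)
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the unique path between every pair of tips.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return symmetric numeric matrix with tip labels as dimnames and zero
#'   diagonal.
#' @export
patristic_distances <- function(tree) {
  validate_phylogeny(tree)
  D <- stats::cophenetic(tree)
  D[tree$tip.label, tree$tip.label]
}

#' Binary host-parasite association matrix
#'
#' @param parasites,hosts character vectors naming the linked pairs
#'   (recycled against each other elementwise).
#' @param parasite_labels,host_labels full label sets (default: the unique
#'   values present).
#' @return binary matrix, parasites in rows, hosts in columns.
#' @export
association_matrix <- function(parasites, hosts,
                               parasite_labels = sort(unique(parasites)),
                               host_labels = sort(unique(hosts))) {
  A <- matrix(0L, length(parasite_labels), length(host_labels),
              dimnames = list(parasite_labels, host_labels))
  A[cbind(match(parasites, parasite_labels), match(hosts, host_labels))] <- 1L
  A
}

#' Expand an association matrix into link pairs
#' @param A binary association matrix (parasites x hosts).
#' @return data.frame with columns `parasite` and `host`, one row per link.
#' @export
expand_links <- function(A) {
  idx <- which(A != 0, arr.ind = TRUE)
  out <- data.frame(parasite = rownames(A)[idx[, 1L]],
                    host = colnames(A)[idx[, 2L]], stringsAsFactors = FALSE)
  out[order(out$parasite, out$host), , drop = FALSE]
}

check_association <- function(A, D_host, D_parasite) {
  if (is.null(rownames(A)) || is.null(colnames(A))) {
    stop("association matrix needs parasite row names and host column names",
         call. = FALSE)
  }
  if (any(rowSums(A != 0) == 0L) || any(colSums(A != 0) == 0L)) {
    stop("input error: association matrix has a row or column with no link",
         call. = FALSE)
  }
  if (!all(rownames(A) %in% rownames(D_parasite)) ||
      !all(colnames(A) %in% rownames(D_host))) {
    stop("association labels missing from distance matrices", call. = FALSE)
  }
  invisible(A)
}

# principal-coordinate axes of a distance matrix: eigen-decomposition of the
# Gower-centred -0.5*D^2 matrix, non-negative axes retained
pcoa_axes <- function(D, tol = 1e-8) {
  n <- nrow(D)
  G <- -0.5 * D * D
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% G %*% C
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  scale0 <- max(abs(e$values), tol)
  keep <- e$values > tol * scale0
  neg <- e$values < -tol * scale0
  neg_mass <- sum(abs(e$values[neg]))
  pos_mass <- sum(e$values[keep])
  B <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                                nrow = sum(keep))
  rownames(B) <- rownames(D)
  list(B = B, negative_fraction = if (pos_mass > 0) neg_mass / pos_mass else 0)
}

#' ParaFit global test of host-parasite cophylogeny
#'
#' Permutation re-implementation of the ParaFit global statistic: hosts and
#' parasites are represented by principal coordinates of their patristic
#' distance matrices (Gower-centred `-0.5 D^2`, non-negative axes), and
#' `ParaFitGlobal = sum(crossprod(B_p, A %*% B_h)^2)`. The null distribution
#' permutes each parasite's host assignments (each row of `A`)
#' independently; the p-value uses the add-one estimator
#' `(1 + #null >= observed) / (1 + n_perm)` and is therefore always in
#' `(0, 1]`.
#'
#' @param D_host,D_parasite patristic distance matrices with tip labels.
#' @param A binary association matrix, parasites in rows, hosts in columns.
#' @param n_perm number of permutations (>= 99; default 10000).
#' @param seed integer seed for the permutation stream.
#' @return a `cophylo_result`: list with `method`, `statistic`, `p_value`,
#'   `n_permutations`, `seed`, and `warnings` (records non-Euclidean
#'   negative-eigenvalue mass above 5%).
#' @export
parafit_test <- function(D_host, D_parasite, A, n_perm = 10000L, seed = 1L) {
  if (n_perm < 99L) stop("n_perm must be >= 99", call. = FALSE)
  check_association(A, D_host, D_parasite)
  hosts <- colnames(A); paras <- rownames(A)
  ph <- pcoa_axes(D_host[hosts, hosts, drop = FALSE])
  pp <- pcoa_axes(D_parasite[paras, paras, drop = FALSE])
  warnings <- character(0)
  if (ph$negative_fraction > 0.05 || pp$negative_fraction > 0.05) {
    warnings <- c(warnings, sprintf(
      "negative eigenvalue mass above 5%% (host %.3f, parasite %.3f)",
      ph$negative_fraction, pp$negative_fraction))
  }
  Bh <- ph$B; Bp <- pp$B
  stat_fun <- function(Am) sum(crossprod(Bp, Am %*% Bh)^2)
  obs <- stat_fun(A)
  nh <- ncol(A)
  set.seed(as.integer(seed))
  null <- vapply(seq_len(n_perm), function(k) {
    Ap <- A
    for (i in seq_len(nrow(A))) Ap[i, ] <- A[i, sample.int(nh)]
    stat_fun(Ap)
  }, numeric(1L))
  p <- (1 + sum(null >= obs)) / (1 + n_perm)
  structure(list(method = "parafit", statistic = obs, p_value = p,
                 n_permutations = as.integer(n_perm), seed = as.integer(seed),
                 warnings = warnings),
            class = "cophylo_result")
}

#' Hommola cospeciation test
#'
#' The statistic is the Pearson correlation between host patristic distances
#' and parasite patristic distances over all unordered pairs of
#' host-parasite links. The null permutes host labels and parasite labels
#' independently; the p-value uses the add-one estimator.
#'
#' @param D_host,D_parasite patristic distance matrices with tip labels.
#' @param links data.frame with columns `parasite` and `host` (>= 3 links),
#'   e.g. from [expand_links()]. Parasites with several hosts contribute one
#'   link per host (pseudo-tip expansion).
#' @param n_perm number of permutations (>= 99; default 10000).
#' @param seed integer seed.
#' @return a `cophylo_result` (see [parafit_test()]); if either distance
#'   vector has zero variance the statistic is `NA` with a `degenerate`
#'   flag.
#' @export
hommola_test <- function(D_host, D_parasite, links, n_perm = 10000L, seed = 1L) {
  if (n_perm < 99L) stop("n_perm must be >= 99", call. = FALSE)
  stopifnot(is.data.frame(links), all(c("parasite", "host") %in% names(links)))
  if (nrow(links) < 3L) stop("need at least 3 links", call. = FALSE)
  hosts <- rownames(D_host); paras <- rownames(D_parasite)
  hi <- match(links$host, hosts); pi <- match(links$parasite, paras)
  if (anyNA(hi) || anyNA(pi)) stop("link labels missing from distance matrices",
                                   call. = FALSE)
  n <- nrow(links)
  pair_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  pair_j <- unlist(lapply(2L:n, function(k) k:n))
  hd <- D_host[cbind(hi[pair_i], hi[pair_j])]
  pd <- D_parasite[cbind(pi[pair_i], pi[pair_j])]
  degenerate <- stats::sd(hd) == 0 || stats::sd(pd) == 0
  if (degenerate) {
    return(structure(list(method = "hommola", statistic = NA_real_,
                          p_value = NA_real_, n_permutations = as.integer(n_perm),
                          seed = as.integer(seed), degenerate = TRUE,
                          warnings = "zero variance in a distance vector"),
                     class = "cophylo_result"))
  }
  obs <- stats::cor(hd, pd)
  nh <- length(hosts); np <- length(paras)
  set.seed(as.integer(seed))
  null <- vapply(seq_len(n_perm), function(k) {
    hperm <- sample.int(nh); pperm <- sample.int(np)
    hdn <- D_host[cbind(hperm[hi[pair_i]], hperm[hi[pair_j]])]
    pdn <- D_parasite[cbind(pperm[pi[pair_i]], pperm[pi[pair_j]])]
    if (stats::sd(hdn) == 0 || stats::sd(pdn) == 0) return(-Inf)
    stats::cor(hdn, pdn)
  }, numeric(1L))
  p <- (1 + sum(null >= obs)) / (1 + n_perm)
  structure(list(method = "hommola", statistic = obs, p_value = p,
                 n_permutations = as.integer(n_perm), seed = as.integer(seed),
                 degenerate = FALSE, warnings = character(0)),
            class = "cophylo_result")
}

#' @export
print.cophylo_result <- function(x, ...) {
  cat(x$method, "test: statistic =", format(x$statistic, digits = 4),
      ", p =", format(x$p_value, digits = 4),
      "(", x$n_permutations, "permutations, seed", x$seed, ")\n")
  if (length(x$warnings)) cat("  warning:", x$warnings, "\n")
  invisible(x)
}

## ---- event-based reconciliation -------------------------------------------

# host-tree topology tables used by the reconciliation scorer
host_tables <- function(tree) {
  n <- ape::Ntip(tree)
  m <- n + tree$Nnode
  kids <- vector("list", m)
  parent <- integer(m)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1L]; b <- tree$edge[k, 2L]
    kids[[a]] <- c(kids[[a]], b)
    parent[b] <- a
  }
  root <- n + 1L
  # subtree membership: desc[[v]] = all nodes in the subtree rooted at v
  desc <- vector("list", m)
  order_nodes <- rev(unique(c(root, tree$edge[, 2L])))  # children before parents
  for (v in order_nodes) {
    desc[[v]] <- c(v, unlist(lapply(kids[[v]], function(w) desc[[w]])))
  }
  list(n_tip = n, n_node = m, kids = kids, parent = parent, root = root,
       desc = desc, is_internal = seq_len(m) > n)
}

# internal host nodes passed through on the directed path a -> b (b inside
# subtree(a)), counting a (if internal and != b) and excluding b
passed_internals <- function(ht, a, b) {
  if (a == b) return(0L)
  cnt <- 0L
  v <- b
  while (v != a) {
    v <- ht$parent[v]
    if (v == 0L) stop("path error: b not below a")
    if (ht$is_internal[v]) cnt <- cnt + 1L
  }
  cnt
}

score_mapping <- function(ht, p_kids, p_internal, phi) {
  codiv <- dup <- loss <- switch_ <- 0L
  for (p in p_internal) {
    h <- phi[p]
    h1 <- phi[p_kids[[p]][1L]]; h2 <- phi[p_kids[[p]][2L]]
    in1 <- h1 %in% ht$desc[[h]]
    in2 <- h2 %in% ht$desc[[h]]
    if (!in1 && !in2) return(NULL)           # invalid: lineage must persist
    if (in1 && in2) {
      side <- NULL
      if (ht$is_internal[h]) {
        kl <- ht$kids[[h]][1L]; kr <- ht$kids[[h]][2L]
        l1 <- h1 %in% ht$desc[[kl]]; r1 <- h1 %in% ht$desc[[kr]]
        l2 <- h2 %in% ht$desc[[kl]]; r2 <- h2 %in% ht$desc[[kr]]
        if (l1 && r2) side <- c(kl, kr)
        else if (r1 && l2) side <- c(kr, kl)
      }
      if (!is.null(side)) {
        codiv <- codiv + 1L
        loss <- loss + passed_internals(ht, side[1L], h1) +
          passed_internals(ht, side[2L], h2)
      } else {
        dup <- dup + 1L
        loss <- loss + passed_internals(ht, h, h1) + passed_internals(ht, h, h2)
      }
    } else {
      switch_ <- switch_ + 1L
      hv <- if (in1) h1 else h2               # the vertically inherited child
      loss <- loss + passed_internals(ht, h, hv)
    }
  }
  c(codivergence = codiv, duplication = dup, loss = loss, host_switch = switch_)
}

#' Exhaustive event-based reconciliation of small cophylogenies
#'
#' Enumerates all mappings of parasite internal nodes onto host tree nodes
#' that are consistent with the tip associations (a parasite lineage must
#' persist on its host lineage: at each parasite divergence at host node
#' `h`, at least one child lineage stays inside the subtree of `h`; a child
#' mapped outside records a host switch). Each mapping is scored with
#' counts of codivergence, duplication, lineage sorting/loss and host
#' switch events; solutions maximising codivergence are returned, ties
#' broken by fewer switches, then duplications, then losses.
#'
#' @param host,parasite rooted binary `phylo` trees (branch lengths are not
#'   used by the scorer).
#' @param A binary association matrix, parasite tips in rows, host tips in
#'   columns; multi-host parasite tips are enumerated over their hosts.
#' @param max_tips refuse trees larger than this (default 8; the search is
#'   exponential).
#' @param polytomy `"refuse"` (default) or `"resolve"` (arbitrary zero-length
#'   resolution via [ape::multi2di()]).
#' @return a `reconciliation_result`: list with `counts` (data.frame of
#'   optimal event counts, one row per optimal solution), `n_optimal`, and
#'   `n_valid` (number of valid mappings enumerated).
#' @export
enumerate_reconciliations <- function(host, parasite, A, max_tips = 8L,
                                      polytomy = c("refuse", "resolve")) {
  polytomy <- match.arg(polytomy)
  validate_phylogeny(host, require_lengths = FALSE)
  validate_phylogeny(parasite, require_lengths = FALSE)
  fix <- function(tr) {
    # a rooted binary tree has exactly Ntip - 1 internal nodes
    if (tr$Nnode != ape::Ntip(tr) - 1L) {
      if (polytomy == "refuse") {
        stop("input error: tree not fully resolved (set polytomy = 'resolve')",
             call. = FALSE)
      }
      tr <- ape::multi2di(tr)
    }
    tr
  }
  host <- fix(host); parasite <- fix(parasite)
  if (ape::Ntip(host) > max_tips || ape::Ntip(parasite) > max_tips) {
    stop("size error: trees exceed max_tips = ", max_tips,
         " (exhaustive search is exponential)", call. = FALSE)
  }
  if (is.null(rownames(A)) || is.null(colnames(A)) ||
      !all(rownames(A) %in% parasite$tip.label) ||
      !all(colnames(A) %in% host$tip.label)) {
    stop("association matrix labels must match tree tip labels", call. = FALSE)
  }
  if (any(rowSums(A != 0) == 0L)) {
    stop("input error: parasite with no host association", call. = FALSE)
  }
  ht <- host_tables(host)
  pt <- host_tables(parasite)
  np_tip <- pt$n_tip
  p_internal <- (np_tip + 1L):pt$n_node
  # parasite nodes in post-order (children before parents)
  post <- rev(unique(c(pt$root, parasite$edge[, 2L])))
  post_internal <- post[post > np_tip]

  # tip association choices
  tip_hosts <- lapply(seq_len(np_tip), function(i) {
    lab <- parasite$tip.label[i]
    if (!lab %in% rownames(A)) return(integer(0))
    hs <- colnames(A)[A[lab, ] != 0]
    match(hs, host$tip.label)
  })
  if (any(lengths(tip_hosts) == 0L)) {
    stop("input error: parasite tip without host association", call. = FALSE)
  }

  solutions <- list()
  n_valid <- 0L
  phi <- integer(pt$n_node)

  assign_internal <- function(k) {
    if (k > length(post_internal)) {
      sc <- score_mapping(ht, pt$kids, p_internal, phi)
      if (!is.null(sc)) {
        n_valid <<- n_valid + 1L
        solutions[[length(solutions) + 1L]] <<- c(sc, phi_key = paste(phi, collapse = "."))
      }
      return(invisible(NULL))
    }
    p <- post_internal[k]
    h1 <- phi[pt$kids[[p]][1L]]; h2 <- phi[pt$kids[[p]][2L]]
    # candidates: ancestors-or-self of either child's host (lineage persists)
    anc_or_self <- function(v) {
      out <- v
      while (v != ht$root) { v <- ht$parent[v]; out <- c(out, v) }
      out
    }
    cands <- unique(c(anc_or_self(h1), anc_or_self(h2)))
    for (h in cands) {
      phi[p] <<- h
      assign_internal(k + 1L)
    }
  }
  assign_tips <- function(i) {
    if (i > np_tip) { assign_internal(1L); return(invisible(NULL)) }
    for (h in tip_hosts[[i]]) {
      phi[i] <<- h
      assign_tips(i + 1L)
    }
  }
  assign_tips(1L)
  if (length(solutions) == 0L) stop("no valid reconciliation found", call. = FALSE)
  tab <- do.call(rbind, lapply(solutions, function(s)
    as.integer(s[c("codivergence", "duplication", "loss", "host_switch")])))
  colnames(tab) <- c("codivergence", "duplication", "loss", "host_switch")
  tab <- as.data.frame(tab)
  ord <- order(-tab$codivergence, tab$host_switch, tab$duplication, tab$loss)
  tab <- tab[ord, , drop = FALSE]
  best <- tab[1L, ]
  opt <- tab[tab$codivergence == best$codivergence &
               tab$host_switch == best$host_switch &
               tab$duplication == best$duplication &
               tab$loss == best$loss, , drop = FALSE]
  opt <- unique(opt)
  rownames(opt) <- NULL
  structure(list(counts = opt, n_optimal = sum(
    tab$codivergence == best$codivergence & tab$host_switch == best$host_switch &
      tab$duplication == best$duplication & tab$loss == best$loss),
    n_valid = n_valid),
    class = "reconciliation_result")
}

#' @export
print.reconciliation_result <- function(x, ...) {
  cat("reconciliation:", x$n_optimal, "optimal mapping(s) of", x$n_valid,
      "valid mappings\n")
  print(x$counts)
  invisible(x)
}

#' Tanglegram export
#'
#' Writes the paired tip orderings of a host and parasite tree together with
#' their links as a plain-text table for external plotting.
#'
#' @param host,parasite `phylo` trees.
#' @param A binary association matrix (parasites x hosts).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_tanglegram <- function(host, parasite, A, path) {
  links <- expand_links(A)
  links$host_order <- match(links$host, host$tip.label)
  links$parasite_order <- match(links$parasite, parasite$tip.label)
  utils::write.table(links, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
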