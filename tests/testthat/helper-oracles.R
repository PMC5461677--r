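# Independent oracles: deliberately plain re-derivations of each quantity,
# written against the definitions rather than the package internals.

# all-pairs percent p-distance by direct double loop over characters
oracle_p_distance <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  used <- 0L; diff <- 0L
  for (i in seq_along(av)) {
    if (av[i] %in% c("-", "N") || bv[i] %in% c("-", "N")) next
    used <- used + 1L
    if (av[i] != bv[i]) diff <- diff + 1L
  }
  100 * diff / used
}

# grouped divergence matrix by brute force over every sequence pair
oracle_divergence_matrix <- function(seqs, groups, statistic = "max") {
  labs <- sort(unique(groups))
  f <- if (statistic == "max") max else mean
  D <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (gi in seq_along(labs)) {
    for (gj in seq_along(labs)) {
      ii <- which(groups == labs[gi]); jj <- which(groups == labs[gj])
      vals <- c()
      for (i in ii) for (j in jj) {
        if (gi == gj && j <= i) next
        vals <- c(vals, oracle_p_distance(seqs[i], seqs[j]))
      }
      D[gi, gj] <- if (length(vals) == 0L) 0 else f(vals)
    }
  }
  D
}

# connected components at a divergence threshold, by breadth-first search
oracle_components <- function(D, thr) {
  n <- nrow(D)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- k
      nb <- which(!is.na(D[v, ]) & D[v, ] <= thr & is.na(comp))
      queue <- c(queue, nb)
    }
  }
  cl <- lapply(split(rownames(D), comp), sort)
  unname(cl[order(vapply(cl, `[`, character(1), 1))])
}

# diagnostic sites by a plain per-column scan
oracle_diagnostic_sites <- function(target, others) {
  tm <- do.call(rbind, strsplit(target, ""))
  om <- do.call(rbind, strsplit(others, ""))
  out <- integer(0)
  for (j in seq_len(ncol(tm))) {
    u <- unique(tm[, j])
    if (length(u) == 1L && u %in% c("A", "C", "G", "T") && !any(om[, j] == u)) {
      out <- c(out, j)
    }
  }
  out
}

# minimum number of multiplex stages by enumerating all set partitions
oracle_min_stages <- function(lengths, tms, sep, window) {
  n <- length(lengths)
  # restricted-growth-string enumeration of set partitions
  best <- n
  rgs <- function(k, s, maxs) {
    if (k > n) {
      groups <- split(seq_len(n), s[seq_len(n)])
      ok <- all(vapply(groups, function(g) {
        if (length(g) >= 2L) {
          dl <- abs(outer(lengths[g], lengths[g], "-"))
          if (any(dl[upper.tri(dl)] < sep)) return(FALSE)
        }
        diff(range(unlist(tms[g]))) <= window
      }, logical(1)))
      if (ok) best <<- min(best, length(groups))
      return(invisible(NULL))
    }
    for (v in seq_len(maxs + 1L)) {
      s[k] <- v
      rgs(k + 1L, s, max(maxs, v))
    }
  }
  s <- integer(n); s[1] <- 1L
  rgs(2L, s, 1L)
  best
}

# exhaustive primer-vs-template scan (both strands, every offset)
oracle_pcr_detections <- function(fwd, rev, template, max_mm = 2L) {
  tv <- strsplit(template, "")[[1]]
  scan <- function(primer, pent_side) {
    pv <- strsplit(primer, "")[[1]]
    l <- length(pv)
    hits <- integer(0)
    if (length(tv) < l) return(hits)
    for (s in 1:(length(tv) - l + 1)) {
      w <- tv[s:(s + l - 1)]
      pent <- if (pent_side == "right") (l - 4):l else 1:5
      if (any(w[pent] != pv[pent])) next
      if (sum(w[-pent] != pv[-pent]) <= max_mm) hits <- c(hits, s)
    }
    hits
  }
  rc <- function(x) paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])),
                          collapse = "")
  fh <- scan(fwd, "right")
  rh <- scan(rc(rev), "left")
  prods <- integer(0)
  for (f in fh) for (r in rh) {
    re <- r + nchar(rev) - 1L
    if (re > f + nchar(fwd) - 1L) prods <- c(prods, re - f + 1L)
  }
  sort(prods)
}

# patristic distances via shortest paths on the weighted tree graph
oracle_patristic <- function(tree) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = tree$edge[, 1], to = tree$edge[, 2]),
    directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  n <- ape::Ntip(tree)
  ids <- as.character(seq_len(n))
  D <- igraph::distances(g, v = ids, to = ids)
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  D
}

# ParaFit global statistic via ape's principal coordinate analysis
oracle_parafit_stat <- function(D_host, D_parasite, A) {
  Bh <- ape::pcoa(D_host[colnames(A), colnames(A)])$vectors
  Bp <- ape::pcoa(D_parasite[rownames(A), rownames(A)])$vectors
  sum((t(Bp) %*% A %*% Bh)^2)
}

# Hommola statistic by direct loops over link pairs
oracle_hommola_stat <- function(D_host, D_parasite, links) {
  hd <- c(); pd <- c()
  for (i in 1:(nrow(links) - 1)) {
    for (j in (i + 1):nrow(links)) {
      hd <- c(hd, D_host[links$host[i], links$host[j]])
      pd <- c(pd, D_parasite[links$parasite[i], links$parasite[j]])
    }
  }
  stats::cor(hd, pd)
}

# exhaustive reconciliation over the full mapping grid, using phangorn's
# ancestor/descendant utilities (independent of the package's host tables)
oracle_reconcile <- function(host, parasite, A) {
  nh <- ape::Ntip(host); np <- ape::Ntip(parasite)
  mh <- nh + host$Nnode
  desc <- lapply(seq_len(mh), function(v)
    c(v, unlist(phangorn::Descendants(host, v, "all"))))
  hkids <- lapply(seq_len(mh), function(v) host$edge[host$edge[, 1] == v, 2])
  losses_on <- function(a, b) {
    if (a == b) return(0L)
    chain <- c(b, phangorn::Ancestors(host, b, "all"))
    ia <- match(a, chain)
    sum(chain[2:ia] > nh)
  }
  pkids <- lapply(seq_len(np + parasite$Nnode), function(v)
    parasite$edge[parasite$edge[, 1] == v, 2])
  p_internal <- (np + 1L):(np + parasite$Nnode)
  tip_map <- vapply(parasite$tip.label, function(lab)
    match(colnames(A)[A[lab, ] != 0][1], host$tip.label), integer(1))
  grid <- do.call(expand.grid, rep(list(seq_len(mh)), length(p_internal)))
  sols <- list()
  for (r in seq_len(nrow(grid))) {
    phi <- c(tip_map, as.integer(grid[r, ]))
    codiv <- dup <- loss <- sw <- 0L
    valid <- TRUE
    for (idx in seq_along(p_internal)) {
      p <- p_internal[idx]
      h <- phi[p]; h1 <- phi[pkids[[p]][1]]; h2 <- phi[pkids[[p]][2]]
      in1 <- h1 %in% desc[[h]]; in2 <- h2 %in% desc[[h]]
      if (!in1 && !in2) { valid <- FALSE; break }
      if (in1 && in2) {
        cod <- FALSE
        if (h > nh) {
          kl <- hkids[[h]][1]; kr <- hkids[[h]][2]
          if (h1 %in% desc[[kl]] && h2 %in% desc[[kr]]) {
            cod <- TRUE; loss <- loss + losses_on(kl, h1) + losses_on(kr, h2)
          } else if (h1 %in% desc[[kr]] && h2 %in% desc[[kl]]) {
            cod <- TRUE; loss <- loss + losses_on(kr, h1) + losses_on(kl, h2)
          }
        }
        if (cod) codiv <- codiv + 1L
        else {
          dup <- dup + 1L
          loss <- loss + losses_on(h, h1) + losses_on(h, h2)
        }
      } else {
        sw <- sw + 1L
        loss <- loss + losses_on(h, if (in1) h1 else h2)
      }
    }
    if (valid) sols[[length(sols) + 1L]] <- c(codiv, dup, loss, sw)
  }
  tab <- do.call(rbind, sols)
  colnames(tab) <- c("codivergence", "duplication", "loss", "host_switch")
  tab <- as.data.frame(tab)
  ord <- order(-tab$codivergence, tab$host_switch, tab$duplication, tab$loss)
  best <- tab[ord[1], ]
  sel <- tab$codivergence == best$codivergence &
    tab$host_switch == best$host_switch &
    tab$duplication == best$duplication & tab$loss == best$loss
  list(counts = unique(tab[sel, , drop = FALSE]), n_optimal = sum(sel))
}

# random aligned sequence strings for property tests
random_seqs <- function(n, len, seed, alphabet = c("A", "C", "G", "T")) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), character(1))
}
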