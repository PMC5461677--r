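#' Simulate a Yule (pure-birth) host phylogeny
#'
#' Starting from two lineages at the root, the waiting time with `k` extant
#' lineages is exponential with rate `k * birth_rate`; a uniformly chosen
#' lineage splits at the end of each waiting time until `n_hosts` lineages
#' exist, after which one final waiting time (rate `n * birth_rate`) elapses
#' to the present so every pendant edge has positive length. The expected
#' root-to-tip depth is `sum(1 / (k * birth_rate))` for `k = 2..n`. The tree
#' is ultrametric and bit-reproducible under `seed`.
#'
#' @param n_hosts number of tips (>= 3).
#' @param birth_rate per-lineage speciation rate.
#' @param seed integer seed.
#' @param tip_prefix prefix for tip labels (default `"H"`).
#' @return a rooted ultrametric `phylo` with tips `H1..Hn`.
#' @export
simulate_host_tree <- function(n_hosts, birth_rate = 1, seed = 1L,
                               tip_prefix = "H") {
  if (n_hosts < 3L) stop("n_hosts must be >= 3", call. = FALSE)
  set.seed(as.integer(seed))
  # lineages: birth time, split time (NA for tips), children indices
  birth <- c(0, 0); split_at <- c(NA_real_, NA_real_)
  children <- list(NULL, NULL)
  active <- c(1L, 2L)
  t_now <- 0
  for (k in 2L:n_hosts) {
    t_now <- t_now + stats::rexp(1L, k * birth_rate)
    if (k == n_hosts) break                    # final interval reaches present
    i <- active[sample.int(length(active), 1L)]
    split_at[i] <- t_now
    id1 <- length(birth) + 1L; id2 <- id1 + 1L
    birth <- c(birth, t_now, t_now)
    split_at <- c(split_at, NA_real_, NA_real_)
    children[[i]] <- c(id1, id2)
    children[[id1]] <- NULL; children[[id2]] <- NULL
    active <- c(setdiff(active, i), id1, id2)
  }
  t_end <- t_now
  tip_counter <- 0L
  nwk <- function(i) {
    end <- if (is.na(split_at[i])) t_end else split_at[i]
    len <- end - birth[i]
    if (is.na(split_at[i])) {
      tip_counter <<- tip_counter + 1L
      sprintf("%s%d:%.10f", tip_prefix, tip_counter, len)
    } else {
      sprintf("(%s,%s):%.10f", nwk(children[[i]][1L]), nwk(children[[i]][2L]), len)
    }
  }
  txt <- sprintf("(%s,%s);", nwk(1L), nwk(2L))
  tree <- ape::read.tree(text = txt)
  validate_phylogeny(tree)
  tree
}

# per-node depth (distance from root) and edge table helpers
node_depths <- function(tree) {
  n <- ape::Ntip(tree)
  d <- ape::node.depth.edgelength(tree)
  d # indexed by node id
}

#' Simulate parasite evolution along a host tree
#'
#' A parasite lineage rides a host branch. At each host divergence the
#' parasite independently codiverges (splits, one daughter per host
#' daughter branch), goes extinct on that host lineage with probability
#' `p_loss` (lineage sorting/loss), or, with probability `p_switch`,
#' diverges with one daughter following a uniformly chosen host daughter
#' and the other jumping to a uniformly chosen contemporary host branch
#' (host switch). At the root divergence, where no external branch exists,
#' a drawn switch is realised as a codivergence. Probabilities must satisfy
#' `p_switch + p_loss <= 1`.
#'
#' @param host ultrametric rooted binary `phylo` (e.g. from
#'   [simulate_host_tree()]).
#' @param p_switch,p_loss per-divergence event probabilities.
#' @param seed integer seed.
#' @return list with `parasite` (`phylo`, or `NULL` if all lineages were
#'   lost), `A` (association matrix, parasite tips x host tips), `empty`
#'   (logical flag), and `true_events` (named counts: codivergence, loss,
#'   host_switch, duplication; duplications are not independently simulated
#'   and always 0).
#' @export
simulate_parasite_evolution <- function(host, p_switch = 0, p_loss = 0, seed = 1L) {
  validate_phylogeny(host)
  if (p_switch < 0 || p_loss < 0 || p_switch + p_loss > 1) {
    stop("need p_switch, p_loss >= 0 and p_switch + p_loss <= 1", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- ape::Ntip(host)
  ht <- host_tables(host)
  depth <- node_depths(host)
  t_end <- max(depth)
  # host edge ending at node v spans (depth[parent[v]], depth[v]]
  edge_birth <- depth[pmax(ht$parent, 1L)]
  edge_birth[ht$parent == 0L] <- 0
  # host internal nodes in time order, root first
  internals <- order(depth[(n + 1L):(n + host$Nnode)]) + n
  events <- c(codivergence = 0L, loss = 0L, host_switch = 0L, duplication = 0L)

  # parasite lineages: riding host edge (child node id), birth time,
  # split time, children
  pl <- list()
  new_lin <- function(host_node, birth) {
    pl[[length(pl) + 1L]] <<- list(host = host_node, birth = birth,
                                   split_at = NA_real_, children = NULL,
                                   alive = TRUE)
    length(pl)
  }
  root_id <- new_lin(ht$root, 0)

  for (v in internals) {
    tv <- depth[v]
    riders <- which(vapply(pl, function(l) l$alive && is.na(l$split_at) &&
                             l$host == v, logical(1L)))
    kids <- ht$kids[[v]]
    for (i in riders) {
      u <- stats::runif(1L)
      if (u < p_loss) {
        pl[[i]]$alive <- FALSE
        pl[[i]]$split_at <- tv
        events["loss"] <- events["loss"] + 1L
      } else if (u < p_loss + p_switch) {
        # contemporary host branches other than v's daughters
        alive_edges <- which(edge_birth <= tv & depth > tv)
        targets <- setdiff(alive_edges, kids)
        pl[[i]]$split_at <- tv
        if (length(targets) == 0L) {
          pl[[i]]$children <- c(new_lin(kids[1L], tv), new_lin(kids[2L], tv))
          events["codivergence"] <- events["codivergence"] + 1L
        } else {
          stay <- kids[sample.int(2L, 1L)]
          jump <- targets[sample.int(length(targets), 1L)]
          pl[[i]]$children <- c(new_lin(stay, tv), new_lin(jump, tv))
          events["host_switch"] <- events["host_switch"] + 1L
        }
      } else {
        pl[[i]]$split_at <- tv
        pl[[i]]$children <- c(new_lin(kids[1L], tv), new_lin(kids[2L], tv))
        events["codivergence"] <- events["codivergence"] + 1L
      }
    }
  }

  # prune dead lineages bottom-up; a lineage survives if it is alive at the
  # present (riding an edge ending in a host tip) or has a surviving child
  survives <- logical(length(pl))
  reaches_tip <- function(i) {
    l <- pl[[i]]
    if (!l$alive) return(FALSE)
    if (is.null(l$children)) return(l$host <= n)
    any(vapply(l$children, reaches_tip, logical(1L)))
  }
  for (i in seq_along(pl)) survives[i] <- reaches_tip(i)
  if (!survives[root_id]) {
    return(list(parasite = NULL, A = NULL, empty = TRUE, true_events = events))
  }

  tip_counter <- 0L
  assoc <- character(0)
  nwk <- function(i) {
    l <- pl[[i]]
    live_kids <- if (is.null(l$children)) integer(0) else
      l$children[survives[l$children]]
    if (length(live_kids) == 0L) {
      tip_counter <<- tip_counter + 1L
      lab <- paste0("P", tip_counter)
      assoc[lab] <<- host$tip.label[l$host]
      end <- if (is.na(l$split_at)) t_end else l$split_at
      sprintf("%s:%.10f", lab, end - l$birth)
    } else if (length(live_kids) == 1L) {
      # suppress the unobserved divergence: splice the surviving child up
      child <- pl[[live_kids]]
      sub <- nwk_spliced(live_kids, l$birth)
      sub
    } else {
      sprintf("(%s,%s):%.10f", nwk(live_kids[1L]), nwk(live_kids[2L]),
              l$split_at - l$birth)
    }
  }
  nwk_spliced <- function(i, birth_override) {
    l <- pl[[i]]
    live_kids <- if (is.null(l$children)) integer(0) else
      l$children[survives[l$children]]
    if (length(live_kids) == 0L) {
      tip_counter <<- tip_counter + 1L
      lab <- paste0("P", tip_counter)
      assoc[lab] <<- host$tip.label[l$host]
      end <- if (is.na(l$split_at)) t_end else l$split_at
      sprintf("%s:%.10f", lab, end - birth_override)
    } else if (length(live_kids) == 1L) {
      nwk_spliced(live_kids, birth_override)
    } else {
      sprintf("(%s,%s):%.10f", nwk(live_kids[1L]), nwk(live_kids[2L]),
              l$split_at - birth_override)
    }
  }
  top <- pl[[root_id]]
  live_root_kids <- if (is.null(top$children)) integer(0) else
    top$children[survives[top$children]]
  if (length(live_root_kids) == 2L) {
    txt <- sprintf("(%s,%s);", nwk(live_root_kids[1L]), nwk(live_root_kids[2L]))
  } else if (length(live_root_kids) == 1L) {
    sub <- nwk_spliced(live_root_kids, pl[[root_id]]$split_at)
    txt <- sprintf("(%s);", sub)
  } else {
    # root parasite itself rides to a tip (no surviving divergence)
    txt <- sprintf("(%s);", nwk_spliced(root_id, 0))
  }
  parasite <- ape::read.tree(text = txt)
  parasite <- ape::collapse.singles(parasite)
  if (ape::Ntip(parasite) < 2L) {
    # a single surviving lineage cannot form a phylogeny
    lab <- names(assoc)[1L]
    A <- matrix(1L, 1L, 1L, dimnames = list(lab, unname(assoc[1L])))
    return(list(parasite = NULL, A = A, empty = FALSE, true_events = events,
                single_lineage = TRUE))
  }
  A <- association_matrix(names(assoc), unname(assoc),
                          parasite_labels = parasite$tip.label,
                          host_labels = host$tip.label)
  list(parasite = parasite, A = A, empty = FALSE, true_events = events)
}

#' Evolve aligned sequences along a tree (Jukes-Cantor)
#'
#' The root sequence is uniform over A/C/G/T; along each branch of length
#' `t`, each site differs from its parent with probability
#' `3/4 * (1 - exp(-4/3 * subst_rate * t))`, changed bases being uniform
#' over the three alternatives (the exact JC69 transition kernel, so no
#' small-step discretisation error).
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param length alignment length in bp (>= 50).
#' @param subst_rate substitutions per site per unit branch length.
#' @param seed integer seed.
#' @param locus locus label for the resulting set.
#' @return an [aligned_seq_set()] with one record per tip (ids = tip labels).
#' @export
evolve_sequences <- function(tree, length = 344L, subst_rate = 1, seed = 1L,
                             locus = "cytb") {
  validate_phylogeny(tree)
  if (length < 50L) stop("alignment length must be >= 50", call. = FALSE)
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  n <- ape::Ntip(tree)
  m <- n + tree$Nnode
  seqs <- vector("list", m)
  root <- n + 1L
  seqs[[root]] <- sample(bases, length, replace = TRUE)
  # cladewise edge order visits parents before children
  tree <- stats::reorder(tree, "cladewise")
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1L]; b <- tree$edge[k, 2L]
    t <- tree$edge.length[k]
    p_change <- 0.75 * (1 - exp(-4 / 3 * subst_rate * t))
    s <- seqs[[a]]
    hit <- stats::runif(length) < p_change
    if (any(hit)) {
      s[hit] <- vapply(s[hit], function(x)
        sample(setdiff(bases, x), 1L), character(1L))
    }
    seqs[[b]] <- s
  }
  tips <- vapply(seq_len(n), function(i) paste(seqs[[i]], collapse = ""),
                 character(1L))
  aligned_seq_set(tree$tip.label, tips, locus = locus)
}

#' Simulate multi-population morphospecies sequence sets
#'
#' Emulates the divergence structure of a cryptic-species complex: a few
#' deeply diverged putative species, each containing several shallowly
#' diverged host populations. Expected between-species p-distance under
#' JC69 is `75 * (1 - exp(-4/3 * d))` percent for path length `d`, so the
#' defaults (deep split ~0.15, shallow ~0.01 substitutions/site) reproduce
#' the empirical pattern of <= ~2.6% within-species versus >= ~8.4%
#' between-species cytb divergence.
#'
#' @param n_species number of cryptic species.
#' @param pops_per_species host populations per species.
#' @param seqs_per_pop sequences per population.
#' @param length alignment length in bp.
#' @param deep,shallow branch lengths (substitutions/site) of the
#'   species-level and population-level splits.
#' @param seed integer seed.
#' @return an [aligned_seq_set()] whose `morphospecies` column holds the
#'   true species (`S1..`) and `host_population` the population (`S1p1..`).
#' @export
simulate_divergent_populations <- function(n_species = 3L, pops_per_species = 2L,
                                           seqs_per_pop = 2L, length = 344L,
                                           deep = 0.15, shallow = 0.01,
                                           seed = 1L) {
  # star-of-stars tree written directly in Newick
  pop_clade <- function(sp, pop) {
    tips <- paste0(sp, pop, "x", seq_len(seqs_per_pop), ":", 0.001)
    if (seqs_per_pop == 1L) tips else
      paste0("(", paste(tips, collapse = ","), "):0")
  }
  sp_clade <- function(sp) {
    pops <- vapply(seq_len(pops_per_species), function(p)
      paste0(pop_clade(sp, paste0("p", p)), ":", shallow / 2), character(1L))
    paste0("(", paste(pops, collapse = ","), "):", deep / 2)
  }
  txt <- paste0("(", paste(vapply(paste0("S", seq_len(n_species)), sp_clade,
                                  character(1L)), collapse = ","), ");")
  tree <- ape::read.tree(text = txt)
  tree <- ape::multi2di(tree)
  tree$edge.length[is.na(tree$edge.length)] <- 0
  seqs <- evolve_sequences(tree, length = length, subst_rate = 1, seed = seed)
  sp <- sub("p[0-9]+x[0-9]+$", "", seqs$records$id)
  pop <- sub("x[0-9]+$", "", seqs$records$id)
  aligned_seq_set(seqs$records$id, seqs$records$seq, locus = seqs$locus,
                  morphospecies = sp, host_population = pop)
}

#' Role map describing the true trophic structure of a simulated community
#'
#' Defaults mirror the structure of a psyllid parasitoid guild: two primary
#' parasitoids, one hyperparasitoid attacking the second primary, and one
#' heteronomous hyperparasitoid whose females develop on the psyllid and
#' whose males develop on the first primary.
#'
#' @param morphospecies,role,prey_female,prey_male equal-length vectors.
#' @return data.frame with those columns.
#' @export
role_map <- function(morphospecies = c("P1", "P2", "H", "HH"),
                     role = c("primary", "primary", "hyperparasitoid",
                              "heteronomous_hyperparasitoid"),
                     prey_female = c("psyllid", "psyllid", "P2", "psyllid"),
                     prey_male = c(NA, "psyllid", "P2", "P1")) {
  out <- data.frame(morphospecies = morphospecies, role = role,
                    prey_female = prey_female, prey_male = prey_male,
                    stringsAsFactors = FALSE)
  hyp <- out[out$role == "hyperparasitoid", , drop = FALSE]
  for (p in stats::na.omit(c(hyp$prey_female, hyp$prey_male))) {
    if (p != "psyllid" && !p %in% out$morphospecies[out$role == "primary"]) {
      stop("hyperparasitoid prey ", p, " is not a primary in the role map",
           call. = FALSE)
    }
  }
  out
}

#' Simulate a mummy detection table with known trophic roles
#'
#' For each morphospecies and sex (females only where `prey_male` is `NA`),
#' `n_per_stratum` post-emergence mummies are generated. Psyllid DNA and
#' emerged-species DNA detections are independent Bernoulli draws with the
#' per-species probabilities in `detect_prob`; given the true role, prey
#' DNA is present with probability 1 (the forensic signal is deterministic,
#' only detectability of the emerged wasp and psyllid is noisy).
#'
#' @param roles a [role_map()].
#' @param n_per_stratum mummies per (species, sex) stratum.
#' @param detect_prob named detection probabilities per species; may include
#'   `psyllid` (defaults to 1); unnamed species default to 1.
#' @param seed integer seed.
#' @param host_species host system label stamped on every record.
#' @return a `mummy_table`.
#' @export
simulate_mummy_table <- function(roles = role_map(), n_per_stratum = 10L,
                                 detect_prob = c(psyllid = 1), seed = 1L,
                                 host_species = "simulated_host") {
  set.seed(as.integer(seed))
  targets <- roles$morphospecies
  dp <- function(sp) {
    if (!is.null(names(detect_prob)) && sp %in% names(detect_prob))
      detect_prob[[sp]] else 1
  }
  rows <- list()
  mummy <- 0L
  for (i in seq_len(nrow(roles))) {
    sp <- roles$morphospecies[i]
    sexes <- c("female", if (!is.na(roles$prey_male[i])) "male")
    for (sx in sexes) {
      prey <- if (sx == "female") roles$prey_female[i] else roles$prey_male[i]
      for (k in seq_len(n_per_stratum)) {
        mummy <- mummy + 1L
        det <- stats::setNames(rep(FALSE, length(targets)), targets)
        det[sp] <- stats::runif(1L) < dp(sp)
        if (!is.na(prey) && prey != "psyllid") det[prey] <- TRUE
        rows[[mummy]] <- c(
          list(mummy_id = sprintf("M%05d", mummy), host_species = host_species,
               emerged_species = sp, emerged_sex = sx,
               psyllid_dna = stats::runif(1L) < dp("psyllid")),
          as.list(stats::setNames(det, paste0("det_", targets))))
      }
    }
  }
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  as_mummy_table(tab)
}

#' Simulate a complete host-parasitoid system
#'
#' Bundles the generators into one internally consistent system: a Yule
#' host tree, a parasite tree evolved along it with the requested
#' host-switch and loss probabilities, per-tip sequences for both trees,
#' the association matrix, a role map and a simulated mummy table. All
#' components share labels and pass the downstream input validators.
#'
#' @param n_hosts host tips.
#' @param birth_rate Yule speciation rate.
#' @param p_switch,p_loss parasite event probabilities per host divergence.
#' @param seq_length alignment length for simulated loci.
#' @param subst_rate substitutions per site per unit branch length.
#' @param n_per_stratum mummies per stratum in the mummy table.
#' @param detect_prob detection probabilities (see [simulate_mummy_table()]).
#' @param seed integer seed controlling every stochastic component.
#' @return list with `host`, `parasite`, `A`, `host_seqs`, `parasite_seqs`,
#'   `roles`, `mummies`, `true_events`, `empty`, `seed`.
#' @export
simulate_system <- function(n_hosts = 8L, birth_rate = 1, p_switch = 0.1,
                            p_loss = 0.05, seq_length = 344L, subst_rate = 0.1,
                            n_per_stratum = 10L,
                            detect_prob = c(psyllid = 0.9, P1 = 0.2, P2 = 0.9,
                                            H = 0.9, HH = 0.9),
                            seed = 1L) {
  seed <- as.integer(seed)
  host <- simulate_host_tree(n_hosts, birth_rate, seed = seed)
  par_sim <- simulate_parasite_evolution(host, p_switch, p_loss, seed = seed + 1L)
  if (par_sim$empty || is.null(par_sim$parasite)) {
    return(list(host = host, parasite = NULL, A = par_sim$A, empty = TRUE,
                true_events = par_sim$true_events, seed = seed))
  }
  host_seqs <- evolve_sequences(host, seq_length, subst_rate, seed = seed + 2L,
                                locus = "COI")
  parasite_seqs <- evolve_sequences(par_sim$parasite, seq_length, subst_rate,
                                    seed = seed + 3L, locus = "cytb")
  roles <- role_map()
  mummies <- simulate_mummy_table(roles, n_per_stratum, detect_prob,
                                  seed = seed + 4L)
  list(host = host, parasite = par_sim$parasite, A = par_sim$A,
       host_seqs = host_seqs, parasite_seqs = parasite_seqs, roles = roles,
       mummies = mummies, true_events = par_sim$true_events, empty = FALSE,
       seed = seed)
}
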