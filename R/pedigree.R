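#' @title Pedigree enumeration and evidence scoring
#' @name pedigree_search
#' @description Kinship algebra on pedigrees, exhaustive enumeration of
#'   small pedigrees with latent individuals compatible with pairwise degree
#'   estimates, sexes and age/date constraints, and additive log-scoring of
#'   candidates against the full evidence set (degrees, mt lineages, birth
#'   intervals, sibling-versus-parent-offspring margins).
NULL

#' Pairwise kinship coefficients of a pedigree
#'
#' Recursive kinship computation: phi(i, i) = (1 + phi(m, f)) / 2,
#' phi(i, j) = (phi(m_i, j) + phi(f_i, j)) / 2 for j not below i. Missing
#' parents contribute zero.
#'
#' @param ped pedigree data.frame (id, sex, mother, father).
#' @return symmetric matrix of kinship coefficients (diagonal is self
#'   kinship, 0.5 without inbreeding).
#' @export
pedigree_kinship <- function(ped) {
  ord <- pedigree_order(ped)  # stops on cycles
  n <- length(ord)
  phi <- matrix(0, n, n, dimnames = list(ord, ord))
  get <- function(a, b) if (is.na(a) || is.na(b)) 0 else phi[a, b]
  for (k in seq_len(n)) {
    i <- ord[k]
    m <- ped$mother[ped$id == i]; f <- ped$father[ped$id == i]
    phi[i, i] <- 0.5 * (1 + get(m, f))
    if (k > 1) for (l in seq_len(k - 1)) {
      j <- ord[l]
      v <- 0.5 * (get(m, j) + get(f, j))
      phi[i, j] <- phi[j, i] <- v
    }
  }
  phi[ped$id, ped$id]
}

#' Relatedness degree from a kinship coefficient
#'
#' degree = round(-log2(4 phi)) + 1 for phi > 0; phi of 1/4, 1/8, 1/16 give
#' degrees 1, 2, 3. Degrees above `max_degree` and phi = 0 report
#' "unrelated"; phi near 1/2 reports "identical".
#'
#' @param phi kinship coefficient(s).
#' @param max_degree largest degree reported as such.
#' @return character vector of degree labels.
#' @export
degree_from_phi <- function(phi, max_degree = 3) {
  vapply(phi, function(p) {
    if (p <= 0) return("unrelated")
    if (p >= 0.4) return("identical")
    d <- round(-log2(4 * p)) + 1
    if (d < 1) d <- 1
    if (d > max_degree) "unrelated" else paste0(switch(d, "1st", "2nd", "3rd"))
  }, "")
}

# evidence accessor: degree for a pair, "undetermined" when absent
evidence_degree <- function(evidence, i, j) {
  d <- evidence$degrees
  hit <- (d$id1 == i & d$id2 == j) | (d$id1 == j & d$id2 == i)
  if (!any(hit)) return(list(degree = "undetermined", confidence = 0))
  list(degree = d$degree[hit][1],
       confidence = if (!is.null(d$confidence)) d$confidence[hit][1] else 1)
}

# maximum kinship compatible with an evidence degree (with slack for
# background inbreeding); used for monotone pruning of partial pedigrees
max_phi_allowed <- function(degree) {
  switch(degree,
         identical = 0.75, "1st" = 0.375, "2nd" = 0.1875,
         "3rd" = 0.09375, unrelated = 0.047, undetermined = 1)
}

# does the pedigree degree match the evidence degree exactly
degree_compatible <- function(ped_degree, ev_degree) {
  if (ev_degree == "undetermined") return(TRUE)
  ped_degree == ev_degree
}

# interval propagation of birth-year bounds along parent-child edges;
# returns refined intervals or NULL if infeasible
propagate_birth_intervals <- function(ped, intervals, gap = c(12, 50)) {
  ids <- ped$id
  lo <- vapply(ids, function(i)
    if (!is.null(intervals[[i]])) intervals[[i]][1] else -1e6, 0)
  hi <- vapply(ids, function(i)
    if (!is.null(intervals[[i]])) intervals[[i]][2] else 1e6, 0)
  names(lo) <- names(hi) <- ids
  for (pass in 1:20) {
    changed <- FALSE
    for (k in seq_along(ids)) {
      for (p in c(ped$mother[k], ped$father[k])) {
        if (is.na(p)) next
        c_id <- ids[k]
        nlo <- max(lo[c_id], lo[p] + gap[1]); nhi <- min(hi[c_id], hi[p] + gap[2])
        plo <- max(lo[p], lo[c_id] - gap[2]); phi_ <- min(hi[p], hi[c_id] - gap[1])
        if (nlo > hi[c_id] + 1e-9 || nhi < lo[c_id] - 1e-9 ||
            plo > hi[p] + 1e-9 || phi_ < lo[p] - 1e-9) {}
        if (nlo > nhi || plo > phi_) return(NULL)
        if (nlo > lo[c_id] || nhi < hi[c_id] ||
            plo > lo[p] || phi_ < hi[p]) changed <- TRUE
        lo[c_id] <- nlo; hi[c_id] <- nhi
        lo[p] <- plo; hi[p] <- phi_
      }
    }
    if (!changed) break
  }
  list(lo = lo, hi = hi)
}

# strip latent founders with at most one child (kinship-neutral) and
# canonicalise latent labels; returns a signature string
canon_signature <- function(ped) {
  repeat {
    drop <- NULL
    for (i in ped$id) {
      r <- ped[ped$id == i, ]
      if (isTRUE(!r$sampled) && is.na(r$mother) && is.na(r$father)) {
        nchild <- sum(ped$mother == i | ped$father == i, na.rm = TRUE)
        if (nchild <= 1) { drop <- i; break }
      }
    }
    if (is.null(drop)) break
    ped$mother[!is.na(ped$mother) & ped$mother == drop] <- NA
    ped$father[!is.na(ped$father) & ped$father == drop] <- NA
    ped <- ped[ped$id != drop, ]
  }
  latents <- ped$id[!ped$sampled]
  edge_str <- function(map) {
    nm <- function(x) ifelse(is.na(x), ".", ifelse(x %in% names(map),
                                                   map[x], x))
    paste(sort(paste0(nm(ped$id), "<", nm(ped$mother), ",",
                      nm(ped$father))), collapse = ";")
  }
  if (length(latents) == 0) return(edge_str(character(0)))
  if (length(latents) > 7) {  # too many to permute; fall back to sorted
    map <- stats::setNames(paste0("L", seq_along(latents)), sort(latents))
    return(edge_str(map))
  }
  perms <- permutations_of(length(latents))
  sigs <- apply(perms, 1, function(p) {
    map <- stats::setNames(paste0("L", p), latents)
    edge_str(map)
  })
  min(sigs)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Enumerate candidate pedigrees compatible with the evidence
#'
#' Depth-first search over parent assignments for every individual. Sampled
#' individuals (oldest first) choose mothers and fathers among existing
#' nodes, "none", or freshly created latent individuals; latent individuals
#' created as parents subsequently choose their own parents among existing
#' nodes or none (latent chains never spawn further latent nodes, which
#' bounds the search while still expressing grandparental, avuncular and
#' half-sib paths through latent connectors). Pruning: monotone kinship
#' bounds (adding edges can only increase kinship), sex-valid parents,
#' acyclicity, birth-interval feasibility, a latent budget, and
#' memoisation of partial states up to latent relabelling. Latent founders
#' with a single child are stripped before final deduplication.
#'
#' @param evidence list with `ids`, `sex` (named), `degrees` (data.frame
#'   id1, id2, degree, confidence), and optionally `birth_interval` (named
#'   list of c(lo, hi) calendar years), `mt_lineage` (named),
#'   `age_at_death` (named list c(lo, hi)), `first_degree_type`.
#' @param max_latent maximum latent individuals.
#' @param max_nodes maximum total nodes.
#' @param generation_gap allowed parent-child birth gap (years).
#' @param cap maximum DFS expansions before returning a partial result.
#' @param no_inbreeding forbid related couples (default TRUE); pedigrees
#'   with consanguineous unions are rarely identifiable from degree
#'   estimates and explode the search space.
#' @return list with `candidates` (list of pedigree data.frames), `complete`
#'   (FALSE when the cap was hit), `n_visited`.
#' @export
enumerate_candidates <- function(evidence, max_latent = 6, max_nodes = 14,
                                 generation_gap = c(12, 50), cap = 200000,
                                 no_inbreeding = TRUE) {
  ids <- evidence$ids
  if (length(ids) > 8) stop("at most 8 sampled individuals supported")
  intervals <- evidence$birth_interval
  mid <- vapply(ids, function(i)
    if (!is.null(intervals[[i]])) mean(intervals[[i]]) else 0, 0)
  ids <- ids[order(mid)]
  ns <- length(ids)
  ev_deg <- matrix("undetermined", ns, ns, dimnames = list(ids, ids))
  for (r in seq_len(nrow(evidence$degrees))) {
    a <- evidence$degrees$id1[r]; b <- evidence$degrees$id2[r]
    if (a %in% ids && b %in% ids)
      ev_deg[a, b] <- ev_deg[b, a] <- evidence$degrees$degree[r]
  }
  deg_code <- c(identical = 0L, "1st" = 1L, "2nd" = 2L, "3rd" = 3L,
                unrelated = 4L, undetermined = 5L)
  ev_codes <- matrix(deg_code[ev_deg], ns, ns)
  ev_maxphi <- apply(ev_deg, 1:2, max_phi_allowed)
  lo0 <- vapply(ids, function(i)
    if (!is.null(intervals[[i]])) intervals[[i]][1] else -1e6, 0)
  hi0 <- vapply(ids, function(i)
    if (!is.null(intervals[[i]])) intervals[[i]][2] else 1e6, 0)

  res <- ped_search_cpp(ns, evidence$sex[ids] == "F",
                        as.integer(t(ev_codes)), as.numeric(t(ev_maxphi)),
                        unname(lo0), unname(hi0),
                        as.integer(max_latent), as.integer(max_nodes),
                        generation_gap[1], generation_gap[2],
                        as.numeric(cap), no_inbreeding, 50000L)

  seen <- new.env(hash = TRUE)
  out <- list()
  for (cand in res$candidates) {
    n <- length(cand$mother)
    nm <- c(ids, if (n > ns) paste0("U", seq_len(n - ns)))
    ped <- data.frame(id = nm, sex = ifelse(cand$sex == 1, "F", "M"),
                      mother = ifelse(cand$mother > 0, nm[pmax(cand$mother, 1)],
                                      NA_character_),
                      father = ifelse(cand$father > 0, nm[pmax(cand$father, 1)],
                                      NA_character_),
                      sampled = seq_len(n) <= ns, stringsAsFactors = FALSE)
    ped <- strip_trivial_latents(ped)
    sig <- canon_signature(ped)
    if (is.null(seen[[sig]])) {
      seen[[sig]] <- TRUE
      out[[length(out) + 1]] <- ped
    }
  }
  list(candidates = out, complete = res$complete, n_visited = res$n_visited)
}

# remove latent founders with at most one child: they do not affect any
# kinship coefficient and make otherwise-identical candidates look distinct
strip_trivial_latents <- function(ped) {
  repeat {
    drop <- NULL
    for (i in ped$id) {
      r <- ped[ped$id == i, ]
      if (isTRUE(!r$sampled) && is.na(r$mother) && is.na(r$father)) {
        nchild <- sum(ped$mother == i | ped$father == i, na.rm = TRUE)
        if (nchild <= 1) { drop <- i; break }
      }
    }
    if (is.null(drop)) break
    ped$mother[!is.na(ped$mother) & ped$mother == drop] <- NA
    ped$father[!is.na(ped$father) & ped$father == drop] <- NA
    ped <- ped[ped$id != drop, , drop = FALSE]
  }
  rownames(ped) <- NULL
  ped
}

#' Score candidate pedigrees against the evidence
#'
#' Additive log-style score: confidence-weighted degree agreement, a hard
#' veto when labelled individuals on one maternal path carry different mt
#' lineages, log-probability of required parent-child birth gaps under
#' independent uniforms on the birth intervals, and sibling/parent-offspring
#' HMM margins where available. Ties keep equal ranks.
#'
#' @param candidates list of pedigree data.frames
#'   (from [enumerate_candidates()]).
#' @param evidence evidence list (see [enumerate_candidates()]).
#' @param generation_gap allowed parent-child gap (years).
#' @param mismatch_penalty per-degree-step penalty for degree disagreement.
#' @return data.frame ranked by decreasing score with columns score, vetoed,
#'   rank, and a `candidates` attribute holding the reordered list.
#' @export
score_candidates <- function(candidates, evidence,
                             generation_gap = c(12, 50),
                             mismatch_penalty = 4) {
  stopifnot(length(candidates) >= 1)
  ids <- evidence$ids
  deg_num <- function(d) switch(d, identical = 0, "1st" = 1, "2nd" = 2,
                                "3rd" = 3, unrelated = 4, NA_integer_)
  score_one <- function(ped) {
    phi <- pedigree_kinship(ped)
    s <- 0; vet <- FALSE
    for (k in utils::combn(ids, 2, simplify = FALSE)) {
      ev <- evidence_degree(evidence, k[1], k[2])
      if (ev$degree == "undetermined") next
      pd <- degree_from_phi(phi[k[1], k[2]])
      diff <- abs(deg_num(pd) - deg_num(ev$degree))
      s <- s - ev$confidence * mismatch_penalty * diff
    }
    # mt lineage hard veto along maternal paths
    if (!is.null(evidence$mt_lineage)) {
      lin <- data.frame(id = names(evidence$mt_lineage),
                        lineage = unname(evidence$mt_lineage),
                        stringsAsFactors = FALSE)
      lin <- lin[lin$id %in% ped$id & !is.na(lin$lineage), ]
      if (nrow(maternal_consistency(lin, ped)) > 0) vet <- TRUE
    }
    # birth-gap probabilities for parent-child edges with dated endpoints
    iv <- evidence$birth_interval
    if (!is.null(iv)) {
      for (k in seq_len(nrow(ped))) {
        for (p in c(ped$mother[k], ped$father[k])) {
          if (is.na(p)) next
          ic <- iv[[ped$id[k]]]; ip <- iv[[p]]
          if (is.null(ic) || is.null(ip)) next
          pr <- gap_probability(ip, ic, generation_gap)
          s <- s + if (pr > 0) log(pr) else -50
        }
      }
    }
    # sibling vs parent-offspring margins
    fdt <- evidence$first_degree_type
    if (!is.null(fdt)) {
      for (r in seq_len(nrow(fdt))) {
        i <- fdt$id1[r]; j <- fdt$id2[r]
        if (!(i %in% ped$id && j %in% ped$id)) next
        is_po <- (!is.na(ped$mother[ped$id == i]) && ped$mother[ped$id == i] == j) ||
                 (!is.na(ped$father[ped$id == i]) && ped$father[ped$id == i] == j) ||
                 (!is.na(ped$mother[ped$id == j]) && ped$mother[ped$id == j] == i) ||
                 (!is.na(ped$father[ped$id == j]) && ped$father[ped$id == j] == i)
        share_m <- !is.na(ped$mother[ped$id == i]) &&
          !is.na(ped$mother[ped$id == j]) &&
          ped$mother[ped$id == i] == ped$mother[ped$id == j]
        share_f <- !is.na(ped$father[ped$id == i]) &&
          !is.na(ped$father[ped$id == j]) &&
          ped$father[ped$id == i] == ped$father[ped$id == j]
        is_sib <- share_m && share_f
        w <- 0.1 * min(fdt$margin[r], 20)
        if (fdt$type[r] == "sibling") s <- s + if (is_sib) w else if (is_po) -w else 0
        if (fdt$type[r] == "parent-offspring")
          s <- s + if (is_po) w else if (is_sib) -w else 0
      }
    }
    list(score = s, vetoed = vet)
  }
  res <- lapply(candidates, score_one)
  df <- data.frame(score = vapply(res, `[[`, 0, "score"),
                   vetoed = vapply(res, `[[`, TRUE, "vetoed"))
  df$score[df$vetoed] <- -Inf
  o <- order(-df$score)
  df <- df[o, , drop = FALSE]
  df$rank <- rank(-df$score, ties.method = "min")
  rownames(df) <- NULL
  attr(df, "candidates") <- candidates[o]
  df
}

# P(gap = b_child - b_parent within window) for independent uniforms on the
# two birth intervals; 1-D quadrature over the parent's interval
gap_probability <- function(ip, ic, window) {
  if (ip[1] == ip[2] && ic[1] == ic[2]) {
    g <- ic[1] - ip[1]
    return(as.numeric(g >= window[1] & g <= window[2]))
  }
  n <- 128
  bp <- seq(ip[1], ip[2], length.out = n)
  wc <- ic[2] - ic[1]
  if (wc == 0) {
    return(mean(ic[1] - bp >= window[1] & ic[1] - bp <= window[2]))
  }
  frac <- pmin(pmax((bp + window[2] - ic[1]) / wc, 0), 1) -
          pmin(pmax((bp + window[1] - ic[1]) / wc, 0), 1)
  mean(frac)
}
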