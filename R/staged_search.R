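#' @title Staged pedigree search for weakly constrained individuals
#' @name staged_search
#' @description When some sampled individuals have no determined degree to
#'   anyone (typical for very low-coverage samples), the space of pedigrees
#'   is unbounded-in-practice: such individuals can attach almost anywhere.
#'   The staged search first enumerates the evidence-constrained core
#'   exhaustively, then attaches the unconstrained individuals one at a
#'   time through an explicit set of attachment moves, keeping a
#'   score-ranked beam between steps.
NULL

# enumerate ways to place `id` (sex sx) into pedigree `ped`:
#  - child of existing node(s) / new latent parents (with optional linking
#    of a new parent to an existing full couple: avuncular paths)
#  - substitute for an existing latent node of the same sex
#  - parent in an empty parent slot of an existing node
#  - floating (unconnected)
attach_options <- function(ped, id, sx) {
  out <- list()
  add <- function(p) out[[length(out) + 1]] <<- p
  # floating
  add(rbind(ped, data.frame(id = id, sex = sx, mother = NA, father = NA,
                            sampled = TRUE, stringsAsFactors = FALSE)))
  females <- ped$id[ped$sex == "F"]
  males <- ped$id[ped$sex == "M"]
  couples <- unique(stats::na.omit(ped[, c("mother", "father")]))
  new_id <- function(ped) {
    k <- nrow(ped) + 1
    while (paste0("U", k) %in% ped$id) k <- k + 1
    paste0("U", k)
  }
  # child of (mo, fa) with mo/fa in existing+NA+NEW
  for (mo in c(NA, females, "NEW")) for (fa in c(NA, males, "NEW")) {
    p2 <- ped
    momo <- mo; fafa <- fa
    newly <- character(0)
    if (identical(mo, "NEW")) {
      momo <- new_id(p2)
      p2 <- rbind(p2, data.frame(id = momo, sex = "F", mother = NA,
                                 father = NA, sampled = FALSE,
                                 stringsAsFactors = FALSE))
      newly <- c(newly, momo)
    }
    if (identical(fa, "NEW")) {
      fafa <- new_id(p2)
      p2 <- rbind(p2, data.frame(id = fafa, sex = "M", mother = NA,
                                 father = NA, sampled = FALSE,
                                 stringsAsFactors = FALSE))
      newly <- c(newly, fafa)
    }
    p2 <- rbind(p2, data.frame(id = id, sex = sx, mother = momo,
                               father = fafa, sampled = TRUE,
                               stringsAsFactors = FALSE))
    add(p2)
    # link each new latent parent to an existing couple (avuncular path)
    for (nl in newly) for (ci in seq_len(nrow(couples))) {
      p3 <- p2
      p3$mother[p3$id == nl] <- couples$mother[ci]
      p3$father[p3$id == nl] <- couples$father[ci]
      add(p3)
    }
  }
  # substitution for a latent node of matching sex
  for (l in ped$id[!ped$sampled & ped$sex == sx]) {
    p2 <- ped
    p2$mother[!is.na(p2$mother) & p2$mother == l] <- id
    p2$father[!is.na(p2$father) & p2$father == l] <- id
    p2$id[p2$id == l] <- id
    p2$sampled[p2$id == id] <- TRUE
    add(p2)
  }
  # parent in an existing empty slot
  slot <- if (sx == "F") "mother" else "father"
  for (k in seq_len(nrow(ped))) {
    if (!is.na(ped[[slot]][k])) next
    p2 <- rbind(ped, data.frame(id = id, sex = sx, mother = NA, father = NA,
                                sampled = TRUE, stringsAsFactors = FALSE))
    p2[[slot]][k] <- id
    add(p2)
  }
  out
}

# quick validity screen for an attachment result
attachment_valid <- function(ped, evidence, generation_gap) {
  phi <- tryCatch(pedigree_kinship(ped), error = function(e) NULL)
  if (is.null(phi)) return(FALSE)
  ids <- intersect(evidence$ids, ped$id)
  for (k in utils::combn(ids, 2, simplify = FALSE)) {
    ev <- evidence_degree(evidence, k[1], k[2])
    if (ev$degree == "undetermined") next
    if (!degree_compatible(degree_from_phi(phi[k[1], k[2]]), ev$degree))
      return(FALSE)
  }
  !is.null(propagate_birth_intervals(ped, evidence$birth_interval,
                                     generation_gap))
}

#' Staged pedigree search: exhaustive core, beam-scored attachments
#'
#' Individuals with at least one determined pairwise degree form the core,
#' which is enumerated exhaustively with [enumerate_candidates()].
#' Remaining individuals are then attached one at a time via explicit
#' attachment moves (child, parent-slot, latent substitution, avuncular
#' linking, floating); after each attachment the candidate list is scored
#' and truncated to `beam` entries.
#'
#' @param evidence evidence list (see [enumerate_candidates()]).
#' @param max_latent latent budget for the core search.
#' @param beam beam width between attachment steps.
#' @param generation_gap allowed parent-child birth gap.
#' @param cap expansion cap for the core search.
#' @return list with `scored` (ranked data.frame, candidates in the
#'   `candidates` attribute), `core_ids`, `attached_ids`, `complete`.
#' @export
staged_pedigree_search <- function(evidence, max_latent = 3, beam = 150,
                                   generation_gap = c(12, 50), cap = 5e6) {
  deg <- evidence$degrees
  det <- deg[deg$degree != "undetermined", ]
  core <- intersect(evidence$ids, unique(c(det$id1, det$id2)))
  rest <- setdiff(evidence$ids, core)
  if (length(core) < 2) { core <- evidence$ids; rest <- character(0) }
  ev_core <- evidence
  ev_core$ids <- core
  res <- enumerate_candidates(ev_core, max_latent = max_latent,
                              generation_gap = generation_gap, cap = cap)
  cands <- res$candidates
  complete <- res$complete
  relaxed_pair <- NULL
  if (length(cands) == 0) {
    # contradictory determined degrees: relax one at a time (least
    # confident first) and report the conflict rather than failing
    dd <- ev_core$degrees
    det_idx <- which(dd$degree != "undetermined" &
                     dd$id1 %in% core & dd$id2 %in% core)
    conf <- if (!is.null(dd$confidence)) dd$confidence[det_idx] else
      rep(1, length(det_idx))
    for (k in det_idx[order(conf)]) {
      ev_try <- ev_core
      ev_try$degrees$degree[k] <- "undetermined"
      res <- enumerate_candidates(ev_try, max_latent = max_latent,
                                  generation_gap = generation_gap,
                                  cap = cap)
      if (length(res$candidates) > 0) {
        cands <- res$candidates
        complete <- FALSE
        relaxed_pair <- c(dd$id1[k], dd$id2[k])
        warning("no pedigree satisfies all determined degrees; relaxed ",
                dd$id1[k], "-", dd$id2[k])
        break
      }
    }
  }
  if (length(cands) == 0)
    return(list(scored = NULL, core_ids = core, attached_ids = rest,
                complete = complete, relaxed_pair = relaxed_pair))
  for (id in rest) {
    sx <- evidence$sex[[id]]
    nxt <- list()
    seen <- new.env(hash = TRUE)
    for (p in cands) {
      for (q in attach_options(p, id, sx)) {
        if (!attachment_valid(q, evidence, generation_gap)) next
        sig <- canon_signature(q)
        if (is.null(seen[[sig]])) {
          seen[[sig]] <- TRUE
          nxt[[length(nxt) + 1]] <- q
        }
      }
    }
    if (length(nxt) == 0) { complete <- FALSE; break }
    sc <- score_candidates(nxt, evidence, generation_gap = generation_gap)
    keep <- seq_len(min(beam, nrow(sc)))
    cands <- attr(sc, "candidates")[keep]
  }
  scored <- score_candidates(cands, evidence, generation_gap = generation_gap)
  list(scored = scored, core_ids = core, attached_ids = rest,
       complete = complete, relaxed_pair = relaxed_pair)
}
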