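#' Enumerate two-way (F1) crosses among a founder panel
#'
#' All distinct unordered pairs of founders. Reciprocal crosses are identified,
#' so \code{A x B} and \code{B x A} are the same cross; for \code{n} founders
#' there are \code{n(n-1)/2} two-way crosses (28 for eight founders).
#'
#' @param founders Either a character vector of unique founder ids or a single
#'   integer \code{n >= 2}, in which case the first \code{n} letters are used.
#' @return A data.frame with columns \code{id}, \code{p1}, \code{p2}; parents
#'   are stored in sorted order so ids are canonical.
#' @examples
#' nrow(enumerate_two_way(8))  # 28
#' @export
enumerate_two_way <- function(founders) {
  founders <- .as_founders(founders, min_n = 2L)
  n <- length(founders)
  idx <- utils::combn(n, 2L)
  p1 <- founders[idx[1L, ]]
  p2 <- founders[idx[2L, ]]
  data.frame(id = paste(p1, p2, sep = "x"), p1 = p1, p2 = p2,
             stringsAsFactors = FALSE)
}

#' Enumerate four-way crosses (pairs of founder-disjoint F1s)
#'
#' A four-way cross is an unordered pair of two-way crosses sharing no founder.
#' For \code{n} founders there are \code{n(n-1)(n-2)(n-3)/8} such crosses
#' (210 for eight founders). With fewer than four founders no disjoint pair
#' exists and an empty table is returned.
#'
#' @inheritParams enumerate_two_way
#' @return A data.frame with columns \code{id}, \code{f1a}, \code{f1b}
#'   (two-way cross ids, sorted) and \code{founders} (comma-separated sorted
#'   founder set of size 4).
#' @examples
#' nrow(enumerate_four_way(8))  # 210
#' @export
enumerate_four_way <- function(founders) {
  founders <- .as_founders(founders, min_n = 2L)
  two <- enumerate_two_way(founders)
  k <- nrow(two)
  out <- list()
  for (i in seq_len(max(k - 1L, 0L))) {
    for (j in seq.int(i + 1L, k)) {
      fs <- c(two$p1[i], two$p2[i], two$p1[j], two$p2[j])
      if (anyDuplicated(fs)) next
      ab <- sort(c(two$id[i], two$id[j]))
      out[[length(out) + 1L]] <- data.frame(
        id = paste(ab, collapse = "_"), f1a = ab[1L], f1b = ab[2L],
        founders = paste(sort(fs), collapse = ","), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(id = character(), f1a = character(), f1b = character(),
                      founders = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- unique(res)
  res[order(res$id), , drop = FALSE]
}

#' Enumerate eight-way crosses (pairs of complementary four-ways)
#'
#' An eight-way cross pairs two four-way crosses whose founder sets are
#' disjoint and together cover all eight founders. The four-way on
#' \code{ABCD} can be paired with each of the three four-ways on
#' \code{EFGH}; over the full 210 four-way crosses on eight founders this
#' yields 315 eight-ways, each four-way participating in exactly three.
#'
#' @param fourways The complete four-way cross table for an eight-founder
#'   panel, as returned by \code{\link{enumerate_four_way}}.
#' @return A data.frame with columns \code{id}, \code{fw1}, \code{fw2}
#'   (four-way ids, sorted).
#' @export
enumerate_eight_way <- function(fourways) {
  founders <- sort(unique(unlist(strsplit(fourways$founders, ",", fixed = TRUE))))
  n <- length(founders)
  if (n != 8L)
    stop("eight-way enumeration requires a four-way table over exactly 8 founders, found ", n)
  expect <- n * (n - 1L) * (n - 2L) * (n - 3L) / 8L
  if (nrow(fourways) != expect || anyDuplicated(fourways$id))
    stop("four-way table is incomplete or inconsistent: expected ", expect,
         " distinct crosses, found ", nrow(fourways))
  sets <- strsplit(fourways$founders, ",", fixed = TRUE)
  out <- list()
  for (i in seq_len(nrow(fourways) - 1L)) {
    for (j in seq.int(i + 1L, nrow(fourways))) {
      if (length(intersect(sets[[i]], sets[[j]]))) next
      ab <- sort(c(fourways$id[i], fourways$id[j]))
      out[[length(out) + 1L]] <- data.frame(
        id = paste(ab, collapse = "__"), fw1 = ab[1L], fw2 = ab[2L],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$id), , drop = FALSE]
}

## Matching machinery on the four-way pairing graph (vertices = four-ways,
## edges = eight-ways; 3-regular for eight founders).  Greedy over a random
## edge order, then alternating-path augmentation; randomized restarts.
.perfect_matching <- function(vertices, edge_a, edge_b, seed, max_restarts = 50L) {
  nv <- length(vertices)
  if (nv %% 2L) stop("odd number of vertices: no perfect matching exists")
  vi <- seq_len(nv)
  names(vi) <- vertices
  ea <- vi[edge_a]; eb <- vi[edge_b]
  adj <- vector("list", nv)
  for (e in seq_along(ea)) {
    adj[[ea[e]]] <- c(adj[[ea[e]]], e)
    adj[[eb[e]]] <- c(adj[[eb[e]]], e)
  }
  other <- function(e, v) if (ea[e] == v) eb[e] else ea[e]
  rng <- .seeded_rng(seed)
  on.exit(rng$restore())
  for (restart in seq_len(max_restarts)) {
    mate <- rep(NA_integer_, nv)          # matched partner vertex
    mate_edge <- rep(NA_integer_, nv)     # edge realizing the match
    for (e in sample.int(length(ea))) {
      if (is.na(mate[ea[e]]) && is.na(mate[eb[e]])) {
        mate[ea[e]] <- eb[e]; mate[eb[e]] <- ea[e]
        mate_edge[ea[e]] <- e; mate_edge[eb[e]] <- e
      }
    }
    # augmenting-path repair (DFS over alternating paths; exact on the
    # bipartite K3,3 components this graph decomposes into)
    augment <- function(v, visited) {
      for (e in adj[[v]]) {
        w <- other(e, v)
        if (visited[w]) next
        visited[w] <- TRUE
        if (is.na(mate[w])) {
          mate[v] <<- w; mate[w] <<- v
          mate_edge[v] <<- e; mate_edge[w] <<- e
          return(TRUE)
        }
        u <- mate[w]
        if (!visited[u]) {
          visited[u] <- TRUE
          if (augment(u, visited)) {
            mate[v] <<- w; mate[w] <<- v
            mate_edge[v] <<- e; mate_edge[w] <<- e
            return(TRUE)
          }
        }
      }
      FALSE
    }
    for (v in vi[is.na(mate)]) {
      if (!is.na(mate[v])) next
      visited <- rep(FALSE, nv); visited[v] <- TRUE
      augment(v, visited)
    }
    if (!anyNA(mate)) return(sort(unique(mate_edge)))
  }
  stop("failed to find a perfect matching after ", max_restarts, " randomized restarts")
}

#' Select a replicated subset of eight-way crosses
#'
#' Chooses eight-way crosses so that every four-way cross is used exactly
#' \code{per_fourway_usage} times. On the eight-founder pairing graph
#' (vertices = four-ways, edges = eight-ways) the maximal usage is 3;
#' usage 2 corresponds to removing a perfect matching (105 of 315 edges),
#' leaving 210 crosses, and usage 1 keeps a perfect matching itself.
#'
#' @param eightways Full eight-way table from \code{\link{enumerate_eight_way}}.
#' @param fourways Full four-way table from \code{\link{enumerate_four_way}}.
#' @param per_fourway_usage Integer in 1..3: times each four-way is used.
#' @param seed Integer seed for the randomized matching search.
#' @return An object of class \code{cross_plan}: a list with elements
#'   \code{founders}, \code{twoways}, \code{fourways}, \code{eightways}
#'   (the selected subset), \code{usage_count} (named integer, per four-way)
#'   and \code{per_fourway_usage}.
#' @examples
#' fw <- enumerate_four_way(8)
#' ew <- enumerate_eight_way(fw)
#' plan <- select_replicated_eight_ways(ew, fw, per_fourway_usage = 2, seed = 1)
#' nrow(plan$eightways)  # 210
#' @export
select_replicated_eight_ways <- function(eightways, fourways,
                                         per_fourway_usage = 2L, seed = 1L) {
  usage <- as.integer(per_fourway_usage)
  if (usage < 1L || usage > 3L)
    stop("per_fourway_usage must be 1, 2 or 3 (the pairing graph is 3-regular)")
  deg <- table(c(eightways$fw1, eightways$fw2))
  if (!all(fourways$id %in% names(deg)) || !all(deg == 3L))
    stop("infeasible: eight-way table is not the full 3-regular pairing graph",
         " (per-four-way degrees: ", paste(sort(unique(deg)), collapse = ","), ")")
  sel <- switch(as.character(usage),
    "3" = seq_len(nrow(eightways)),
    "1" = .perfect_matching(fourways$id, eightways$fw1, eightways$fw2, seed),
    "2" = setdiff(seq_len(nrow(eightways)),
                  .perfect_matching(fourways$id, eightways$fw1, eightways$fw2, seed)))
  chosen <- eightways[sel, , drop = FALSE]
  rownames(chosen) <- NULL
  cnt <- table(factor(c(chosen$fw1, chosen$fw2), levels = fourways$id))
  if (!all(cnt == usage))
    stop("internal error: selected subset does not use every four-way exactly ",
         usage, " times")
  founders <- sort(unique(unlist(strsplit(fourways$founders, ",", fixed = TRUE))))
  plan <- list(founders = founders,
               twoways = enumerate_two_way(founders),
               fourways = fourways,
               eightways = chosen,
               usage_count = stats::setNames(as.integer(cnt), names(cnt)),
               per_fourway_usage = usage,
               seed = seed)
  class(plan) <- "cross_plan"
  plan
}

#' @export
print.cross_plan <- function(x, ...) {
  cat("MAGIC funnel cross plan\n")
  cat("  founders:   ", paste(x$founders, collapse = " "), "\n")
  cat("  two-ways:   ", nrow(x$twoways), "\n")
  cat("  four-ways:  ", nrow(x$fourways), "\n")
  cat("  eight-ways: ", nrow(x$eightways),
      sprintf(" (each four-way used %d time%s)\n", x$per_fourway_usage,
              if (x$per_fourway_usage > 1L) "s" else ""))
  invisible(x)
}

.cross_tier <- function(plan, id) {
  if (id %in% plan$eightways$id) return("eightway")
  if (id %in% plan$fourways$id) return("fourway")
  if (id %in% plan$twoways$id) return("twoway")
  NA_character_
}

.cross_founders <- function(id) {
  sort(unique(unlist(strsplit(id, "[x_]+"))))
}

#' Substitute a failed cross by its most closely related cross
#'
#' When a cross in the plan fails, seed from the most closely related cross of
#' the same tier is substituted. Relatedness is scored by shared structure:
#' founder-set overlap, refined (for four- and eight-way crosses) by the number
#' of shared sub-cross components. Ties are broken lexicographically on cross
#' id, making the substitution deterministic.
#'
#' @param plan A \code{cross_plan}.
#' @param failed_cross_id Id of the failed cross (any tier present in the plan).
#' @return The id of the substitute cross.
#' @export
substitute_failed_cross <- function(plan, failed_cross_id) {
  tier <- .cross_tier(plan, failed_cross_id)
  if (is.na(tier)) stop("cross ", failed_cross_id, " is not in the plan")
  pool <- switch(tier, twoway = plan$twoways$id, fourway = plan$fourways$id,
                 eightway = plan$eightways$id)
  cand <- setdiff(pool, failed_cross_id)
  if (!length(cand)) stop("no candidate cross of tier '", tier, "' available")
  score <- vapply(cand, .relatedness_score, numeric(1), ref = failed_cross_id)
  best <- cand[score == max(score)]
  sort(best)[1L]
}

## shared founders, weighted by shared exact components at each tier
.relatedness_score <- function(id, ref) {
  f_overlap <- length(intersect(.cross_founders(id), .cross_founders(ref)))
  two_ref <- unlist(strsplit(ref, "_+")); two_id <- unlist(strsplit(id, "_+"))
  fw_ref <- unlist(strsplit(ref, "__", fixed = TRUE))
  fw_id <- unlist(strsplit(id, "__", fixed = TRUE))
  shared_fw <- if (grepl("__", ref, fixed = TRUE))
    length(intersect(fw_id, fw_ref)) else 0L
  shared_two <- length(intersect(two_id, two_ref))
  f_overlap + 2L * shared_two + 8L * shared_fw
}

#' Allocate recombinant inbred lines to eight-way families
#'
#' Divides a target number of lines among families as equally as possible:
#' counts differ by at most one, with the larger counts going to the
#' lexicographically first families so the allocation is deterministic.
#'
#' @param families Character vector of eight-way family ids.
#' @param total_lines Total number of RILs to allocate.
#' @return Named integer vector of per-family counts summing to
#'   \code{total_lines}.
#' @examples
#' table(allocate_rils(paste0("fam", 1:210), 1091))  # 169 fives, 41 sixes
#' @export
allocate_rils <- function(families, total_lines) {
  if (!length(families)) stop("at least one family is required")
  if (anyDuplicated(families)) stop("family ids must be unique")
  total_lines <- as.integer(total_lines)
  if (total_lines < 0L) stop("total_lines must be non-negative")
  fam <- sort(families)
  k <- length(fam)
  base <- total_lines %/% k
  extra <- total_lines %% k
  counts <- rep.int(base, k)
  if (extra > 0L) counts[seq_len(extra)] <- base + 1L
  stats::setNames(counts, fam)[families]
}

#' Build the pedigree skeleton for single-seed-descent RILs
#'
#' Each RIL descends from its own eight-way F1 individual, advanced by
#' \code{ssd_generations} selfings. Eight-way progeny are labelled F1, so the
#' terminal lines carry generation label F(\code{ssd_generations} + 1); six
#' selfing generations give F7 lines.
#'
#' @param plan A \code{cross_plan}.
#' @param allocation Named per-family line counts from
#'   \code{\link{allocate_rils}} (names must be eight-way ids in the plan).
#' @param ssd_generations Number of selfing generations (>= 0).
#' @return An object of class \code{magic_pedigree}: a data.frame with columns
#'   \code{line_id}, \code{family_id}, \code{generation}, \code{parent_id}
#'   (the cross id for F1 individuals, otherwise the previous selfing
#'   generation), with attribute \code{ssd_generations}. Terminal lines have
#'   ids \code{L0001, L0002, ...}; intermediate generations append
#'   \code{_F<g>}.
#' @export
build_pedigree <- function(plan, allocation, ssd_generations = 6L) {
  t <- as.integer(ssd_generations)
  if (t < 0L) stop("ssd_generations must be >= 0")
  fams <- names(allocation)
  if (is.null(fams) || !all(fams %in% plan$eightways$id))
    stop("allocation names must be eight-way family ids present in the plan")
  n_total <- sum(allocation)
  line_ids <- sprintf("L%04d", seq_len(n_total))
  fam_of_line <- rep(fams, times = allocation)
  # ids laid out as a (t+1) x n matrix: one selfing chain per column
  gens <- seq_len(t + 1L)
  ids <- matrix(paste0(rep(line_ids, each = t + 1L), "_F", gens),
                nrow = t + 1L)
  ids[t + 1L, ] <- line_ids
  parents <- rbind(fam_of_line,
                   if (t > 0L) ids[-(t + 1L), , drop = FALSE])
  ped <- data.frame(line_id = as.vector(ids),
                    family_id = rep(fam_of_line, each = t + 1L),
                    generation = paste0("F", gens),
                    parent_id = as.vector(parents),
                    stringsAsFactors = FALSE)
  attr(ped, "ssd_generations") <- t
  class(ped) <- c("magic_pedigree", "data.frame")
  ped
}

#' Terminal lines of a pedigree
#'
#' @param pedigree A \code{magic_pedigree}.
#' @return Character vector of terminal (most advanced generation) line ids.
#' @export
pedigree_lines <- function(pedigree) {
  t <- attr(pedigree, "ssd_generations")
  pedigree$line_id[pedigree$generation == paste0("F", t + 1L)]
}

#' Derive association-scan strata from a pedigree
#'
#' Assigns each terminal line to a funnel (its eight-way family) and to a
#' cross-within-funnel stratum (the eight-way F1 individual it descends from),
#' the two variance-component strata used by the pedigree-aware scan.
#'
#' @param pedigree A \code{magic_pedigree}.
#' @return data.frame with columns \code{line}, \code{funnel}, \code{cross}.
#' @export
derive_strata <- function(pedigree) {
  lines <- pedigree_lines(pedigree)
  idx <- match(lines, pedigree$line_id)
  fam <- pedigree$family_id[idx]
  # walk each terminal line back to its F1 ancestor, one generation at a time
  t <- attr(pedigree, "ssd_generations")
  f1_of <- lines
  for (g in seq_len(t))
    f1_of <- pedigree$parent_id[match(f1_of, pedigree$line_id)]
  data.frame(line = lines, funnel = fam, cross = f1_of,
             stringsAsFactors = FALSE)
}

.as_founders <- function(founders, min_n = 2L) {
  if (is.numeric(founders) && length(founders) == 1L) {
    n <- as.integer(founders)
    if (n < min_n) stop("at least ", min_n, " founders are required")
    if (n > 26L) stop("more than 26 founders: supply explicit ids")
    founders <- LETTERS[seq_len(n)]
  }
  founders <- as.character(founders)
  if (length(founders) < min_n) stop("at least ", min_n, " founders are required")
  if (anyDuplicated(founders)) stop("founder ids must be unique")
  if (any(grepl("[x_]", founders)))
    stop("founder ids must not contain 'x' or '_' (reserved as cross-id separators)")
  sort(founders)
}

## run a block of code under a temporary seed, restoring the caller's RNG
.seeded_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  rng <- .seeded_rng(seed)
  on.exit(rng$restore())
  expr
}
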