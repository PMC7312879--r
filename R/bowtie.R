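#' Bow-tie risk model
#'
#' A bow tie joins a fault tree (causes, left side) and an event tree
#' (consequences, right side) at a central top event. Preventive safety
#' barriers sit on the cause side, mitigative barriers on the consequence
#' side. The structure here is purely qualitative: it carries no
#' frequencies or probabilities, so severity and likelihood cannot be
#' quantified from it — it is a map of causes, consequences and the
#' safety measures addressing them.
#'
#' Causes and consequences may be given as bare character vectors of
#' labels (identifiers `c1..`, `q1..` are generated) or as data.frames
#' with columns `id` and `label`. Barriers may be character vectors
#' (identifiers `pb1..`/`mb1..` generated, not attached to a specific
#' branch) or data.frames with `id`, `label` and `target`, where
#' `target` names the cause (preventive) or consequence (mitigative) the
#' barrier protects; `NA` targets attach the barrier to the side as a
#' whole.
#'
#' @param top_event single string naming the central event.
#' @param causes causes on the fault-tree side (>= 1).
#' @param consequences consequences on the event-tree side (>= 1).
#' @param preventive_barriers barriers on the cause side.
#' @param mitigative_barriers barriers on the consequence side.
#' @param notes optional free-text annotation carried through
#'   serialization.
#' @return An object of class `bowtie`.
#' @seealso [validate_bowtie()], [bowtie_to_json()], [bowtie_to_dot()],
#'   [metallurgy_bowtie()] for the packaged worked example.
#' @export
bowtie <- function(top_event, causes, consequences,
                   preventive_barriers = character(),
                   mitigative_barriers = character(), notes = "") {
  as_nodes <- function(x, prefix) {
    if (is.data.frame(x)) {
      stopifnot(all(c("id", "label") %in% names(x)))
      data.frame(id = as.character(x$id), label = as.character(x$label))
    } else {
      x <- as.character(x)
      data.frame(id = if (length(x)) paste0(prefix, seq_along(x))
                      else character(),
                 label = x)
    }
  }
  as_barriers <- function(x, prefix) {
    if (is.data.frame(x)) {
      stopifnot(all(c("id", "label") %in% names(x)))
      data.frame(id = as.character(x$id), label = as.character(x$label),
                 target = if (is.null(x$target)) NA_character_
                          else as.character(x$target))
    } else {
      x <- as.character(x)
      data.frame(id = if (length(x)) paste0(prefix, seq_along(x))
                      else character(),
                 label = x, target = rep(NA_character_, length(x)))
    }
  }
  structure(
    list(top_event = as.character(top_event)[1L],
         causes = as_nodes(causes, "c"),
         consequences = as_nodes(consequences, "q"),
         preventive_barriers = as_barriers(preventive_barriers, "pb"),
         mitigative_barriers = as_barriers(mitigative_barriers, "mb"),
         notes = as.character(notes)[1L]),
    class = "bowtie"
  )
}

#' Validate a bow tie
#'
#' Checks structural invariants and returns all violations found:
#' a non-empty top event, at least one cause and one consequence, unique
#' node identifiers across the whole diagram, and barrier targets that
#' resolve to an existing cause (preventive) or consequence (mitigative).
#'
#' @param bt a [bowtie()].
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_bowtie <- function(bt) {
  stopifnot(inherits(bt, "bowtie"))
  v <- character()
  if (!nzchar(trimws(bt$top_event)))
    v <- c(v, "top event is empty")
  if (nrow(bt$causes) == 0L)
    v <- c(v, "bow tie has no causes")
  if (nrow(bt$consequences) == 0L)
    v <- c(v, "bow tie has no consequences")
  ids <- c(bt$causes$id, bt$consequences$id, bt$preventive_barriers$id,
           bt$mitigative_barriers$id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    v <- c(v, paste("duplicate node identifiers:",
                    paste(dup, collapse = ", ")))
  dangling <- function(barriers, nodes, side) {
    tg <- barriers$target
    bad <- !is.na(tg) & !(tg %in% nodes$id)
    if (any(bad))
      paste0("dangling ", side, " barrier reference: ",
             paste(barriers$id[bad], "->", tg[bad], collapse = ", "))
  }
  v <- c(v, dangling(bt$preventive_barriers, bt$causes, "preventive"),
         dangling(bt$mitigative_barriers, bt$consequences, "mitigative"))
  v
}

#' @export
print.bowtie <- function(x, ...) {
  cat("Bow tie:", x$top_event, "\n")
  cat(sprintf("  %d causes, %d consequences, %d preventive / %d mitigative barriers\n",
              nrow(x$causes), nrow(x$consequences),
              nrow(x$preventive_barriers), nrow(x$mitigative_barriers)))
  v <- validate_bowtie(x)
  if (length(v)) cat("  INVALID:", paste(v, collapse = "; "), "\n")
  invisible(x)
}

#' Serialize a bow tie to JSON and back
#'
#' The JSON form is lossless and canonical (stable field order, no
#' number rounding), so export -> import -> export is byte-identical.
#'
#' @param bt a [bowtie()].
#' @return `bowtie_to_json()` a JSON string; `bowtie_from_json()` a
#'   `bowtie` object.
#' @export
bowtie_to_json <- function(bt) {
  stopifnot(inherits(bt, "bowtie"))
  jsonlite::toJSON(
    list(top_event = bt$top_event, causes = bt$causes,
         consequences = bt$consequences,
         preventive_barriers = bt$preventive_barriers,
         mitigative_barriers = bt$mitigative_barriers,
         notes = bt$notes),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
}

#' @rdname bowtie_to_json
#' @param json a JSON string or path to a JSON file.
#' @export
bowtie_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  empty_barriers <- data.frame(id = character(), label = character(),
                               target = character())
  as_df <- function(x, cols) {
    if (is.null(x) || length(x) == 0L)
      return(empty_barriers[, cols, drop = FALSE])
    as.data.frame(x)[, cols, drop = FALSE]
  }
  bowtie(
    top_event = obj$top_event,
    causes = as_df(obj$causes, c("id", "label")),
    consequences = as_df(obj$consequences, c("id", "label")),
    preventive_barriers = as_df(obj$preventive_barriers,
                                c("id", "label", "target")),
    mitigative_barriers = as_df(obj$mitigative_barriers,
                                c("id", "label", "target")),
    notes = if (is.null(obj$notes)) "" else obj$notes
  )
}

#' Export a bow tie to Graphviz DOT
#'
#' Renders the diagram left to right: causes, preventive barriers, top
#' event, mitigative barriers, consequences. A barrier with a target is
#' placed on the path of its branch (cause -> barrier -> top event, or
#' top event -> barrier -> consequence); untargeted barriers attach
#' directly to the top event. Refuses invalid bow ties, reporting the
#' violations.
#'
#' @param bt a valid [bowtie()].
#' @return A single string of DOT source. The number of declared nodes
#'   is `1 + causes + consequences + barriers`.
#' @export
bowtie_to_dot <- function(bt) {
  v <- validate_bowtie(bt)
  if (length(v))
    stop("refusing to export invalid bow tie: ",
         paste(v, collapse = "; "), call. = FALSE)
  q <- function(s) paste0('"', gsub('"', '\\\\"', s), '"')
  lines <- c("digraph bowtie {", "  rankdir=LR;",
             paste0("  top [label=", q(bt$top_event),
                    ", shape=doubleoctagon];"))
  node <- function(df, shape) {
    if (nrow(df) == 0L) return(character())
    sprintf("  %s [label=%s, shape=%s];", df$id, q(df$label), shape)
  }
  lines <- c(lines,
             node(bt$causes, "box"),
             node(bt$consequences, "box"),
             node(bt$preventive_barriers, "note"),
             node(bt$mitigative_barriers, "note"))
  edges <- character()
  pb <- bt$preventive_barriers
  for (cid in bt$causes$id) {
    via <- pb$id[!is.na(pb$target) & pb$target == cid]
    if (length(via))
      edges <- c(edges, sprintf("  %s -> %s;", cid, via),
                 sprintf("  %s -> top;", via))
    else edges <- c(edges, sprintf("  %s -> top;", cid))
  }
  edges <- c(edges, sprintf("  %s -> top [style=dashed];",
                            pb$id[is.na(pb$target)]))
  mb <- bt$mitigative_barriers
  for (qid in bt$consequences$id) {
    via <- mb$id[!is.na(mb$target) & mb$target == qid]
    if (length(via))
      edges <- c(edges, sprintf("  top -> %s;", via),
                 sprintf("  %s -> %s;", via, qid))
    else edges <- c(edges, sprintf("  top -> %s;", qid))
  }
  edges <- c(edges, sprintf("  top -> %s [style=dashed];",
                            mb$id[is.na(mb$target)]))
  paste(c(lines, edges, "}"), collapse = "\n")
}
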