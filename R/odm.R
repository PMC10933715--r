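#' @title CDISC ODM bridge
#'
#' @description
#' Interoperability with metadata registries that speak CDISC ODM 1.3:
#' [odm_export()] serializes an annotated Questionnaire to an ODM study
#' definition whose ItemDefs carry the logical-model path in an Alias tag
#' (context `"gecco-path"`) and whose CodeListItems carry the option
#' codings as Alias tags (context = code-system URI, name = code);
#' [parse_odm()] reads such a document back; [convert_odm()] turns a
#' parsed study into an annotated FHIR Questionnaire compatible with
#' [map_response()], translating collection conditions to enableWhen and —
#' when a code-list item carries several codings — selecting the coding
#' system used by a reference Questionnaire.
#'
#' ODM ItemGroupDefs do not nest, so the export flattens the item tree into
#' one ItemGroupDef per top-level branch; per-leaf paths, question texts,
#' option codings and effective enable conditions survive the round trip
#' (see [questionnaire_equivalent()]).
#'
#' @name odm-bridge
NULL

ODM_NS <- "http://www.cdisc.org/ns/odm/v1.3"
GECCO_PATH_CONTEXT <- "gecco-path"

odm_datatype_for <- function(type) {
  switch(type,
    choice = "text", date = "date", dateTime = "datetime",
    quantity = "float", integer = "integer", "text")
}

item_type_for_odm <- function(datatype, has_codelist, has_unit) {
  if (has_codelist) return("choice")
  switch(datatype,
    date = "date", datetime = "dateTime",
    float = if (has_unit) "quantity" else "quantity",
    integer = "integer", "string")
}

# Effective enable condition of a leaf item: its own enableWhen if present,
# else the innermost enclosing group's.  Returns NULL or
# list(question = <linkId>, answerCoding = <coding>).
effective_condition <- function(item, inherited) {
  ew <- item$enableWhen
  if (!is.null(ew) && length(ew) > 0) {
    list(question = ew[[1]]$question, answerCoding = ew[[1]]$answerCoding)
  } else inherited
}

#' Export an annotated Questionnaire as a CDISC ODM study definition
#'
#' @param questionnaire An annotated FHIR R4 Questionnaire (every
#'   non-group item must carry a `compass-gecco-item` path extension).
#' @param path Optional file to write the XML to.
#' @return An `xml2::xml_document`.
#' @export
odm_export <- function(questionnaire, path = NULL) {
  check_questionnaire(questionnaire)

  leaves <- list()        # per-leaf export records
  groups <- list()        # top-level branch -> leaf OIDs
  conditions <- list()    # key -> list(oid, item_oid, coded_value)
  linkid_to_path <- character(0)

  items_all <- flatten_items(questionnaire)
  for (it in items_all) {
    p <- item_gecco_path(it)
    if (!is.na(p)) linkid_to_path[it$linkId] <- p
  }

  walk <- function(items, branch, inherited) {
    for (it in items) {
      cond <- effective_condition(it, inherited)
      if (identical(it$type, "group")) {
        b <- if (is.null(branch)) it else branch
        walk(it$item %||% list(), b, cond)
      } else {
        p <- item_gecco_path(it)
        gecco_abort_if(is.na(p), "invalid_questionnaire",
                       sprintf("item '%s' carries no path annotation; cannot export", it$linkId))
        rec <- list(item = it, path = p, condition = cond,
                    branch_name = if (!is.null(branch)) branch$text else "items",
                    branch_key = if (!is.null(branch))
                      item_gecco_path(branch) %||% branch$linkId else "items")
        leaves[[length(leaves) + 1L]] <<- rec
        walk(it$item %||% list(), branch, cond)
      }
    }
  }
  walk(questionnaire$item %||% list(), NULL, NULL)

  doc <- xml2::xml_new_root("ODM", xmlns = ODM_NS,
                            FileOID = "ODM.geccomap", FileType = "Snapshot",
                            ODMVersion = "1.3",
                            CreationDateTime = "1970-01-01T00:00:00")
  study <- xml2::xml_add_child(doc, "Study", OID = "S.geccomap")
  gv <- xml2::xml_add_child(study, "GlobalVariables")
  xml2::xml_add_child(gv, "StudyName", questionnaire$title %||% "questionnaire")
  xml2::xml_add_child(gv, "StudyDescription", "exported questionnaire")
  xml2::xml_add_child(gv, "ProtocolName", questionnaire$name %||% "questionnaire")
  mdv <- xml2::xml_add_child(study, "MetaDataVersion", OID = "MDV.1",
                             Name = "export")
  form <- xml2::xml_add_child(mdv, "FormDef", OID = "F.1",
                              Name = questionnaire$title %||% "form",
                              Repeating = "No")
  if (!is.null(questionnaire$url)) {
    xml2::xml_add_child(form, "Alias", Context = "form-url",
                        Name = questionnaire$url)
  }

  group_oid <- function(key) paste0("IG.", gsub("[^A-Za-z0-9.]", "_", key))
  item_oid <- function(p) paste0("I.", p)

  # group leaves by top-level branch, preserving document order
  branch_keys <- unique(vapply(leaves, `[[`, character(1), "branch_key"))
  for (bk in branch_keys) {
    xml2::xml_add_child(form, "ItemGroupRef", ItemGroupOID = group_oid(bk),
                        Mandatory = "No")
  }

  cond_oid_for <- function(cond) {
    key <- paste(cond$question, cond$answerCoding$code, sep = "|")
    if (is.null(conditions[[key]])) {
      ctrl_path <- if (cond$question %in% names(linkid_to_path))
        linkid_to_path[[cond$question]] else NULL
      gecco_abort_if(is.null(ctrl_path), "invalid_questionnaire",
                     sprintf("enableWhen controls unannotated item '%s'", cond$question))
      conditions[[key]] <<- list(
        oid = sprintf("C.%d", length(conditions) + 1L),
        item_oid = item_oid(ctrl_path),
        coded_value = cond$answerCoding$code)
    }
    conditions[[key]]$oid
  }

  for (bk in branch_keys) {
    in_branch <- Filter(function(r) identical(r$branch_key, bk), leaves)
    ig <- xml2::xml_add_child(mdv, "ItemGroupDef", OID = group_oid(bk),
                              Name = in_branch[[1]]$branch_name %||% bk,
                              Repeating = "No")
    for (rec in in_branch) {
      ref <- xml2::xml_add_child(ig, "ItemRef", ItemOID = item_oid(rec$path),
                                 Mandatory = "No")
      if (!is.null(rec$condition)) {
        xml2::xml_set_attr(ref, "CollectionExceptionConditionOID",
                           cond_oid_for(rec$condition))
      }
    }
  }

  for (rec in leaves) {
    it <- rec$item
    idef <- xml2::xml_add_child(mdv, "ItemDef", OID = item_oid(rec$path),
                                Name = rec$path,
                                DataType = odm_datatype_for(it$type))
    q <- xml2::xml_add_child(idef, "Question")
    tt <- xml2::xml_add_child(q, "TranslatedText", it$text %||% rec$path)
    xml2::xml_set_attr(tt, "xml:lang", "en")
    if (!is.null(it$answerOption)) {
      xml2::xml_add_child(idef, "CodeListRef",
                          CodeListOID = paste0("CL.", rec$path))
    }
    xml2::xml_add_child(idef, "Alias", Context = GECCO_PATH_CONTEXT,
                        Name = rec$path)
    unit <- item_ext_value(it, "questionnaire-unit", "valueCoding")
    if (!is.null(unit)) {
      xml2::xml_add_child(idef, "Alias", Context = "ucum-unit", Name = unit$code)
    }
  }

  for (rec in leaves) {
    it <- rec$item
    if (is.null(it$answerOption)) next
    cl <- xml2::xml_add_child(mdv, "CodeList", OID = paste0("CL.", rec$path),
                              Name = rec$path, DataType = "text")
    for (opt in it$answerOption) {
      cd <- opt$valueCoding
      cli <- xml2::xml_add_child(cl, "CodeListItem", CodedValue = cd$code)
      dec <- xml2::xml_add_child(cli, "Decode")
      tt <- xml2::xml_add_child(dec, "TranslatedText", cd$display %||% cd$code)
      xml2::xml_set_attr(tt, "xml:lang", "en")
      xml2::xml_add_child(cli, "Alias", Context = cd$system, Name = cd$code)
    }
  }

  for (key in names(conditions)) {
    cond <- conditions[[key]]
    cdef <- xml2::xml_add_child(mdv, "ConditionDef", OID = cond$oid,
                                Name = cond$oid)
    fe <- xml2::xml_add_child(
      cdef, "FormalExpression",
      sprintf('%s == "%s"', cond$item_oid, cond$coded_value))
    xml2::xml_set_attr(fe, "Context", "mdm-equality")
  }

  if (!is.null(path)) xml2::write_xml(doc, path)
  doc
}

odm_find <- function(node, xpath) {
  xml2::xml_find_all(node, xpath, ns = c(odm = ODM_NS))
}

#' Parse a CDISC ODM study definition
#'
#' Reads the study-definition subset used by this package (FormDef,
#' ItemGroupDef/ItemRef, ItemDef with Question/CodeListRef/Alias, CodeList
#' with coded Alias tags, ConditionDef with an equality FormalExpression).
#' Unknown metadata elements are skipped with a warning.
#'
#' @param source Path to an ODM XML file, an XML string, or an
#'   `xml2::xml_document`.
#' @return An `odm_study` list with components `form`, `groups`, `items`,
#'   `code_lists` and `conditions`.
#' @export
parse_odm <- function(source) {
  doc <- tryCatch(
    # re-reading an in-memory document through text normalizes namespaces
    xml2::read_xml(if (inherits(source, "xml_document")) as.character(source)
                   else source),
    error = function(e) stop_gecco("parse", paste("malformed ODM XML:",
                                                  conditionMessage(e)))
  )
  mdv <- odm_find(doc, ".//odm:MetaDataVersion")
  gecco_abort_if(length(mdv) == 0, "parse", "ODM document has no MetaDataVersion")
  mdv <- mdv[[1]]

  known <- c("FormDef", "ItemGroupDef", "ItemDef", "CodeList", "ConditionDef",
             "Include", "Protocol", "StudyEventDef", "MethodDef")
  kids <- xml2::xml_name(xml2::xml_children(mdv))
  unknown <- setdiff(unique(kids), known)
  if (length(unknown) > 0)
    warning(sprintf("ignoring unknown ODM metadata elements: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)

  attr_or_null <- function(x, a) {
    v <- xml2::xml_attr(x, a)
    if (is.na(v)) NULL else v
  }
  aliases_of <- function(node) {
    lapply(odm_find(node, "./odm:Alias"), function(a) {
      list(context = xml2::xml_attr(a, "Context"),
           name = xml2::xml_attr(a, "Name"))
    })
  }

  form_node <- odm_find(mdv, "./odm:FormDef")
  form <- if (length(form_node) > 0) {
    fa <- aliases_of(form_node[[1]])
    url <- NULL
    for (al in fa) if (identical(al$context, "form-url")) url <- al$name
    list(oid = xml2::xml_attr(form_node[[1]], "OID"),
         name = attr_or_null(form_node[[1]], "Name"),
         url = url,
         group_oids = vapply(odm_find(form_node[[1]], "./odm:ItemGroupRef"),
                             function(r) xml2::xml_attr(r, "ItemGroupOID"),
                             character(1)))
  } else list(oid = NULL, name = NULL, url = NULL, group_oids = character(0))

  groups <- lapply(odm_find(mdv, "./odm:ItemGroupDef"), function(g) {
    list(oid = xml2::xml_attr(g, "OID"),
         name = attr_or_null(g, "Name"),
         item_refs = lapply(odm_find(g, "./odm:ItemRef"), function(r) {
           list(item_oid = xml2::xml_attr(r, "ItemOID"),
                condition_oid = attr_or_null(r, "CollectionExceptionConditionOID"))
         }))
  })
  names(groups) <- vapply(groups, `[[`, character(1), "oid")

  items <- lapply(odm_find(mdv, "./odm:ItemDef"), function(it) {
    clref <- odm_find(it, "./odm:CodeListRef")
    qtext <- odm_find(it, "./odm:Question/odm:TranslatedText")
    list(oid = xml2::xml_attr(it, "OID"),
         name = attr_or_null(it, "Name"),
         datatype = attr_or_null(it, "DataType") %||% "text",
         question = if (length(qtext) > 0) xml2::xml_text(qtext[[1]]) else NULL,
         codelist_oid = if (length(clref) > 0)
           xml2::xml_attr(clref[[1]], "CodeListOID") else NULL,
         aliases = aliases_of(it))
  })
  names(items) <- vapply(items, `[[`, character(1), "oid")

  code_lists <- lapply(odm_find(mdv, "./odm:CodeList"), function(cl) {
    list(oid = xml2::xml_attr(cl, "OID"),
         items = lapply(odm_find(cl, "./odm:CodeListItem"), function(cli) {
           dtext <- odm_find(cli, "./odm:Decode/odm:TranslatedText")
           list(coded_value = xml2::xml_attr(cli, "CodedValue"),
                decode = if (length(dtext) > 0) xml2::xml_text(dtext[[1]]) else NULL,
                aliases = aliases_of(cli))
         }))
  })
  names(code_lists) <- vapply(code_lists, `[[`, character(1), "oid")

  conditions <- lapply(odm_find(mdv, "./odm:ConditionDef"), function(cd) {
    fe <- odm_find(cd, "./odm:FormalExpression")
    list(oid = xml2::xml_attr(cd, "OID"),
         expression = if (length(fe) > 0) xml2::xml_text(fe[[1]]) else NULL,
         context = if (length(fe) > 0) xml2::xml_attr(fe[[1]], "Context") else NULL)
  })
  names(conditions) <- vapply(conditions, `[[`, character(1), "oid")

  # referential integrity
  for (it in items) {
    gecco_abort_if(!is.null(it$codelist_oid) && is.null(code_lists[[it$codelist_oid]]),
                   "reference",
                   sprintf("ItemDef '%s' references missing CodeList '%s'",
                           it$oid, it$codelist_oid))
  }
  for (g in groups) {
    for (ref in g$item_refs) {
      gecco_abort_if(is.null(items[[ref$item_oid]]), "reference",
                     sprintf("ItemGroupDef '%s' references missing ItemDef '%s'",
                             g$oid, ref$item_oid))
      gecco_abort_if(!is.null(ref$condition_oid) &&
                       is.null(conditions[[ref$condition_oid]]),
                     "reference",
                     sprintf("ItemRef '%s' references missing ConditionDef '%s'",
                             ref$item_oid, ref$condition_oid))
    }
  }

  structure(list(form = form, groups = groups, items = items,
                 code_lists = code_lists, conditions = conditions),
            class = "odm_study")
}

#' @export
print.odm_study <- function(x, ...) {
  cat(sprintf("<odm_study> form '%s': %d groups, %d items, %d code lists, %d conditions\n",
              x$form$name %||% "<unnamed>", length(x$groups), length(x$items),
              length(x$code_lists), length(x$conditions)))
  invisible(x)
}

parse_condition_expression <- function(cond) {
  expr <- cond$expression %||% ""
  m <- regmatches(expr, regexec('^\\s*([A-Za-z0-9._-]+)\\s*==\\s*"([^"]*)"\\s*$', expr))[[1]]
  gecco_abort_if(length(m) != 3, "unsupported_condition",
                 sprintf("ConditionDef '%s': unsupported expression '%s' (only <item> == \"<code>\" is supported)",
                         cond$oid, expr))
  list(item_oid = m[2], coded_value = m[3])
}

alias_path <- function(aliases) {
  for (al in aliases) if (identical(al$context, GECCO_PATH_CONTEXT)) return(al$name)
  NULL
}

# Coding aliases (context looks like a URI) of a code-list item.
coding_aliases <- function(aliases) {
  Filter(function(al) grepl("^(https?|urn):", al$context %||% ""), aliases)
}

#' Convert a parsed ODM study into an annotated FHIR Questionnaire
#'
#' One Questionnaire item is created per ODM item; the `gecco-path` Alias
#' becomes the path annotation extension, collection conditions become
#' enableWhen, and each answerOption carries exactly one coding.  When a
#' CodeListItem carries aliases from several code systems the system used
#' by the `reference` Questionnaire for the same model path decides;
#' without a reference this is an error.
#'
#' @param study An `odm_study` from [parse_odm()].
#' @param reference Optional annotated reference Questionnaire used to
#'   disambiguate multi-coded code-list items.
#' @return A FHIR R4 Questionnaire list; its `url` is the source form's
#'   URL when the ODM carries one.
#' @export
convert_odm <- function(study, reference = NULL) {
  stopifnot(inherits(study, "odm_study"))

  # reference lookup: model path -> option codings
  ref_options <- list()
  if (!is.null(reference)) {
    for (it in flatten_items(reference)) {
      p <- item_gecco_path(it)
      if (!is.na(p) && !is.null(it$answerOption)) {
        ref_options[[p]] <- lapply(it$answerOption, `[[`, "valueCoding")
      }
    }
  }

  pick_coding <- function(aliases, decode, path, coded_value) {
    cands <- coding_aliases(aliases)
    if (length(cands) == 0) {
      # uncoded code-list entry: keep the coded value as a local code
      return(list(system = "urn:odm:codelist", code = coded_value,
                  display = decode %||% coded_value))
    }
    chosen <- NULL
    if (length(cands) == 1) {
      chosen <- cands[[1]]
    } else {
      refs <- ref_options[[path %||% ""]] %||% list()
      ref_systems <- vapply(refs, function(cd) cd$system %||% "", character(1))
      for (cand in cands) {
        if (cand$context %in% ref_systems) { chosen <- cand; break }
      }
      gecco_abort_if(is.null(chosen), "ambiguous_coding",
                     sprintf("code-list value '%s' carries %d codings and no reference questionnaire resolves the system",
                             coded_value, length(cands)))
    }
    out <- list(system = chosen$context, code = chosen$name)
    if (!is.null(decode)) out$display <- decode
    out
  }

  # Document-order list of (group, item) pairs from the form.
  group_oids <- if (length(study$form$group_oids) > 0) study$form$group_oids
                else names(study$groups)
  items <- list()
  oid_to_linkid <- character(0)
  gi <- 0L
  for (goid in group_oids) {
    g <- study$groups[[goid]]
    if (is.null(g)) next
    gi <- gi + 1L
    group_item <- list(linkId = linkid_scheme(gi),
                       text = g$name %||% goid, type = "group",
                       required = FALSE)
    kids <- list()
    for (j in seq_along(g$item_refs)) {
      ref <- g$item_refs[[j]]
      idef <- study$items[[ref$item_oid]]
      lid <- linkid_scheme(c(gi, j))
      oid_to_linkid[idef$oid] <- lid
      path <- alias_path(idef$aliases)
      unit <- NULL
      for (al in idef$aliases) if (identical(al$context, "ucum-unit")) unit <- al$name
      qi <- list(linkId = lid, text = idef$question %||% idef$name,
                 type = item_type_for_odm(idef$datatype,
                                          !is.null(idef$codelist_oid),
                                          !is.null(unit)))
      if (!is.null(idef$codelist_oid)) {
        cl <- study$code_lists[[idef$codelist_oid]]
        qi$answerOption <- lapply(cl$items, function(cli) {
          list(valueCoding = pick_coding(cli$aliases, cli$decode, path,
                                         cli$coded_value))
        })
      }
      qi$required <- FALSE
      ext <- list()
      if (!is.null(path)) {
        ext <- c(ext, list(list(
          url = paste0("https://example.org/fhir/compass", ITEM_EXT_SUFFIX),
          valueString = path)))
      }
      if (!is.null(unit)) {
        ext <- c(ext, list(list(
          url = "http://hl7.org/fhir/StructureDefinition/questionnaire-unit",
          valueCoding = list(system = SYSTEMS$ucum, code = unit))))
      }
      if (length(ext) > 0) qi$extension <- ext
      qi$condition_oid <- ref$condition_oid  # resolved in a second pass
      kids[[length(kids) + 1L]] <- qi
    }
    group_item$item <- kids
    items[[length(items) + 1L]] <- group_item
  }

  # second pass: conditions -> enableWhen (need all linkIds assigned)
  for (a in seq_along(items)) {
    for (b in seq_along(items[[a]]$item)) {
      qi <- items[[a]]$item[[b]]
      coid <- qi$condition_oid
      qi$condition_oid <- NULL
      if (!is.null(coid)) {
        parsed <- parse_condition_expression(study$conditions[[coid]])
        ctrl_lid <- if (parsed$item_oid %in% names(oid_to_linkid))
          oid_to_linkid[[parsed$item_oid]] else NULL
        gecco_abort_if(is.null(ctrl_lid), "reference",
                       sprintf("condition '%s' controls item '%s' which is not in the form",
                               coid, parsed$item_oid))
        # recover system/display from the controlling item's options
        ctrl <- NULL
        for (aa in seq_along(items)) for (bb in seq_along(items[[aa]]$item)) {
          if (identical(items[[aa]]$item[[bb]]$linkId, ctrl_lid))
            ctrl <- items[[aa]]$item[[bb]]
        }
        answer <- list(code = parsed$coded_value)
        for (opt in ctrl$answerOption %||% list()) {
          if (identical(opt$valueCoding$code, parsed$coded_value))
            answer <- opt$valueCoding
        }
        qi$enableWhen <- list(list(question = ctrl_lid, operator = "=",
                                   answerCoding = answer))
      }
      items[[a]]$item[[b]] <- qi
    }
  }

  q <- list(
    resourceType = "Questionnaire",
    url = study$form$url %||% paste0("urn:odm:", study$form$oid %||% "form"),
    version = "1.0.0",
    name = gsub("[^A-Za-z0-9]", "_", study$form$name %||% "converted"),
    title = study$form$name %||% "converted",
    status = "active"
  )
  if (length(items) > 0) q$item <- items
  q
}

# ---- semantic equivalence comparator -----------------------------------

leaf_summary <- function(questionnaire) {
  out <- list()
  linkid_to_path <- character(0)
  for (it in flatten_items(questionnaire)) {
    p <- item_gecco_path(it)
    if (!is.na(p)) linkid_to_path[it$linkId] <- p
  }
  walk <- function(items, inherited) {
    for (it in items) {
      cond <- effective_condition(it, inherited)
      if (identical(it$type, "group")) {
        walk(it$item %||% list(), cond)
      } else {
        p <- item_gecco_path(it)
        codings <- vapply(it$answerOption %||% list(), function(o) {
          paste(o$valueCoding$system %||% "", o$valueCoding$code, sep = "|")
        }, character(1))
        cond_key <- if (is.null(cond)) "" else {
          ctrl <- linkid_to_path[cond$question]
          paste(if (is.na(ctrl)) cond$question else unname(ctrl),
                cond$answerCoding$code, sep = "=")
        }
        out[[p %||% it$linkId]] <<- list(
          text = it$text %||% "",
          options = sort(codings),
          condition = cond_key)
        walk(it$item %||% list(), cond)
      }
    }
  }
  walk(questionnaire$item %||% list(), NULL)
  out
}

#' Compare two questionnaires for semantic equivalence
#'
#' Two questionnaires are considered equivalent when they define the same
#' set of model paths and, per path, the same question text, the same set
#' of answer-option codings, and the same effective enable condition
#' (controlling path and required code) — regardless of linkIds or group
#' nesting.  This is the comparator behind the ODM round-trip guarantee.
#'
#' @param a,b FHIR Questionnaires.
#' @return `TRUE` or `FALSE`; differences are reported as an attribute
#'   `"differences"` when `FALSE`.
#' @export
questionnaire_equivalent <- function(a, b) {
  sa <- leaf_summary(a)
  sb <- leaf_summary(b)
  diffs <- character(0)
  if (!setequal(names(sa), names(sb))) {
    diffs <- c(diffs, sprintf("path sets differ: only in a: %s; only in b: %s",
                              paste(setdiff(names(sa), names(sb)), collapse = ","),
                              paste(setdiff(names(sb), names(sa)), collapse = ",")))
  } else {
    for (p in names(sa)) {
      if (!identical(sa[[p]]$text, sb[[p]]$text))
        diffs <- c(diffs, sprintf("%s: text differs ('%s' vs '%s')",
                                  p, sa[[p]]$text, sb[[p]]$text))
      if (!identical(sa[[p]]$options, sb[[p]]$options))
        diffs <- c(diffs, sprintf("%s: option codings differ", p))
      if (!identical(sa[[p]]$condition, sb[[p]]$condition))
        diffs <- c(diffs, sprintf("%s: enable condition differs ('%s' vs '%s')",
                                  p, sa[[p]]$condition, sb[[p]]$condition))
    }
  }
  ok <- length(diffs) == 0
  if (!ok) attr(ok, "differences") <- diffs
  ok
}
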