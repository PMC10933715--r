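# Crafted fixtures shared by the conformance and acceptance suites.

# A known-good bundle covering all seven resource types, to break in
# controlled ways.
good_bundle <- function(model) {
  r <- make_response(list(
    "consent.dataProcessing" = yes_answer(),
    "vitalSigns.bodyTemperature" = list(valueQuantity = list(
      value = 38.1, unit = "Cel", system = "http://unitsofmeasure.org",
      code = "Cel")),
    "anamnesis.hasChronicLungDisease" = no_answer(),
    "medication.aceInhibitors" = yes_answer(),
    "vaccination.covid19" = yes_answer(),
    "vaccination.covid19.date" = list(valueDate = "2021-04-01"),
    "therapy.dialysis" = list(valueDate = "2021-02-11")
  ))
  map_response(r, model)
}

break_resource <- function(bundle, type, fun) {
  for (i in seq_along(bundle$entry)) {
    if (identical(bundle$entry[[i]]$resource$resourceType, type)) {
      bundle$entry[[i]]$resource <- fun(bundle$entry[[i]]$resource)
      return(bundle)
    }
  }
  stop("no such resource type in bundle: ", type)
}

# ODM fixture whose code-list items deliberately carry two codings each.
multi_coded_odm <- function() {
  '<?xml version="1.0" encoding="UTF-8"?>
<ODM xmlns="http://www.cdisc.org/ns/odm/v1.3" FileOID="ODM.t" FileType="Snapshot" ODMVersion="1.3" CreationDateTime="1970-01-01T00:00:00">
 <Study OID="S.t">
  <GlobalVariables><StudyName>t</StudyName><StudyDescription/><ProtocolName>t</ProtocolName></GlobalVariables>
  <MetaDataVersion OID="MDV.1" Name="t">
   <FormDef OID="F.1" Name="t" Repeating="No">
    <ItemGroupRef ItemGroupOID="IG.1" Mandatory="No"/>
   </FormDef>
   <ItemGroupDef OID="IG.1" Name="Anamnesis" Repeating="No">
    <ItemRef ItemOID="I.anamnesis.hasChronicLungDisease" Mandatory="No"/>
   </ItemGroupDef>
   <ItemDef OID="I.anamnesis.hasChronicLungDisease" Name="gate" DataType="text">
    <Question><TranslatedText xml:lang="en">Does the patient suffer from a chronic lung disease?</TranslatedText></Question>
    <CodeListRef CodeListOID="CL.1"/>
    <Alias Context="gecco-path" Name="anamnesis.hasChronicLungDisease"/>
   </ItemDef>
   <CodeList OID="CL.1" Name="yn" DataType="text">
    <CodeListItem CodedValue="373066001">
     <Decode><TranslatedText xml:lang="en">Yes</TranslatedText></Decode>
     <Alias Context="http://snomed.info/sct" Name="373066001"/>
     <Alias Context="http://loinc.org" Name="LA33-6"/>
    </CodeListItem>
    <CodeListItem CodedValue="373067005">
     <Decode><TranslatedText xml:lang="en">No</TranslatedText></Decode>
     <Alias Context="http://snomed.info/sct" Name="373067005"/>
     <Alias Context="http://loinc.org" Name="LA32-8"/>
    </CodeListItem>
   </CodeList>
  </MetaDataVersion>
 </Study>
</ODM>'
}
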