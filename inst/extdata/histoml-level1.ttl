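@prefix histo: <https://histoml.example/histoml#> .
@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .

<https://histoml.example/histoml> a owl:Ontology .
histo:AnatomicalStructure a owl:Class .
histo:AnatomicalStructure rdfs:subClassOf histo:PhysicalEntity .
histo:Architectural_Pattern a owl:Class .
histo:Architectural_Pattern rdfs:subClassOf histo:Phenotype .
histo:Capillary a owl:Class .
histo:Capillary rdfs:subClassOf histo:AnatomicalStructure .
histo:Cell a owl:Class .
histo:Cell rdfs:subClassOf histo:PhysicalEntity .
histo:CellularComponent a owl:Class .
histo:CellularComponent rdfs:subClassOf histo:PhysicalEntity .
histo:Cellular_Appearances a owl:Class .
histo:Cellular_Appearances rdfs:subClassOf histo:Phenotype .
histo:CytoplasmicInclusion a owl:Class .
histo:CytoplasmicInclusion rdfs:subClassOf histo:CellularComponent .
histo:Data a owl:Class .
histo:Endothelium a owl:Class .
histo:Endothelium rdfs:subClassOf histo:Cell .
histo:Endothelium rdfs:subClassOf histo:NormalEntity .
histo:Entity a owl:Class .
histo:EntityAttribute a owl:Class .
histo:EntityAttribute rdfs:subClassOf histo:Utility .
histo:EntityReference a owl:Class .
histo:EntityReference rdfs:subClassOf histo:Utility .
histo:Erythrocyte a owl:Class .
histo:Erythrocyte rdfs:subClassOf histo:Cell .
histo:Erythrocyte rdfs:subClassOf histo:NormalEntity .
histo:Glycogen a owl:Class .
histo:Glycogen rdfs:subClassOf histo:Substance .
histo:Lymphocyte a owl:Class .
histo:Lymphocyte rdfs:subClassOf histo:Cell .
histo:Lymphocyte rdfs:subClassOf histo:NormalEntity .
histo:Mucin a owl:Class .
histo:Mucin rdfs:subClassOf histo:Substance .
histo:NeoplasticArea a owl:Class .
histo:NeoplasticArea rdfs:subClassOf histo:Tissue .
histo:NeoplasticArea rdfs:subClassOf histo:Tumor .
histo:NeoplasticCell a owl:Class .
histo:NeoplasticCell rdfs:subClassOf histo:Cell .
histo:NeoplasticCell rdfs:subClassOf histo:Tumor .
histo:NormalEntity a owl:Class .
histo:NormalEntity rdfs:subClassOf histo:PhysicalEntity .
histo:Nucleolus a owl:Class .
histo:Nucleolus rdfs:subClassOf histo:CellularComponent .
histo:Nucleus a owl:Class .
histo:Nucleus rdfs:subClassOf histo:CellularComponent .
histo:Parenchyma a owl:Class .
histo:Parenchyma rdfs:subClassOf histo:Tissue .
histo:Phenotype a owl:Class .
histo:Phenotype rdfs:subClassOf histo:Entity .
histo:PhysicalEntity a owl:Class .
histo:PhysicalEntity rdfs:subClassOf histo:Entity .
histo:Product_or_Reserve a owl:Class .
histo:Product_or_Reserve rdfs:subClassOf histo:Phenotype .
histo:Quantification a owl:Class .
histo:Quantification rdfs:subClassOf histo:Utility .
histo:Relationship a owl:Class .
histo:Relationship rdfs:subClassOf histo:Utility .
histo:RenalSinus a owl:Class .
histo:RenalSinus rdfs:subClassOf histo:AnatomicalStructure .
histo:Stroma a owl:Class .
histo:Stroma rdfs:subClassOf histo:Tissue .
histo:Substance a owl:Class .
histo:Substance rdfs:subClassOf histo:PhysicalEntity .
histo:Tissue a owl:Class .
histo:Tissue rdfs:subClassOf histo:PhysicalEntity .
histo:Tumor a owl:Class .
histo:Tumor rdfs:subClassOf histo:PhysicalEntity .
histo:Utility a owl:Class .
histo:WholeSlideImage a owl:Class .
histo:WholeSlideImage rdfs:subClassOf histo:Data .
histo:Xref a owl:Class .
histo:Xref rdfs:subClassOf histo:Utility .
histo:entityReference a owl:ObjectProperty .
histo:entityReference rdfs:domain histo:PhysicalEntity .
histo:entityReference rdfs:range histo:EntityReference .
histo:formula a owl:DatatypeProperty .
histo:formula rdfs:domain histo:Quantification .
histo:formula rdfs:range xsd:string .
histo:hasAnatomicalEntity a owl:ObjectProperty .
histo:hasAnatomicalEntity rdfs:domain histo:PhysicalEntity .
histo:hasAnatomicalEntity rdfs:range histo:AnatomicalStructure .
histo:hasAnatomicalEntity rdfs:subPropertyOf histo:hasComponent .
histo:hasAttribute a owl:ObjectProperty .
histo:hasAttribute rdfs:domain histo:PhysicalEntity .
histo:hasAttribute rdfs:range histo:EntityAttribute .
histo:hasCell a owl:ObjectProperty .
histo:hasCell rdfs:domain histo:PhysicalEntity .
histo:hasCell rdfs:range histo:Cell .
histo:hasCell rdfs:subPropertyOf histo:hasComponent .
histo:hasCellularComponent a owl:ObjectProperty .
histo:hasCellularComponent rdfs:domain histo:PhysicalEntity .
histo:hasCellularComponent rdfs:range histo:CellularComponent .
histo:hasCellularComponent rdfs:subPropertyOf histo:hasComponent .
histo:hasComponent a owl:ObjectProperty .
histo:hasComponent rdfs:domain histo:PhysicalEntity .
histo:hasComponent rdfs:range histo:PhysicalEntity .
histo:hasProduct a owl:ObjectProperty .
histo:hasProduct rdfs:domain histo:PhysicalEntity .
histo:hasProduct rdfs:range histo:Substance .
histo:hasQuantification a owl:ObjectProperty .
histo:hasQuantification rdfs:domain histo:EntityAttribute .
histo:hasQuantification rdfs:range histo:Quantification .
histo:hasRelationship a owl:ObjectProperty .
histo:hasRelationship rdfs:domain histo:Phenotype .
histo:hasRelationship rdfs:range histo:Relationship .
histo:hasReserve a owl:ObjectProperty .
histo:hasReserve rdfs:domain histo:Cell .
histo:hasReserve rdfs:range histo:Substance .
histo:hasXref a owl:ObjectProperty .
histo:hasXref rdfs:range histo:Xref .
histo:height a owl:DatatypeProperty .
histo:height rdfs:domain histo:WholeSlideImage .
histo:height rdfs:range xsd:integer .
histo:magnification a owl:DatatypeProperty .
histo:magnification rdfs:domain histo:WholeSlideImage .
histo:magnification rdfs:range xsd:decimal .
histo:micronsPerPixel a owl:DatatypeProperty .
histo:micronsPerPixel rdfs:domain histo:WholeSlideImage .
histo:micronsPerPixel rdfs:range xsd:decimal .
histo:movementType a owl:DatatypeProperty .
histo:movementType rdfs:domain histo:Relationship .
histo:movementType rdfs:range xsd:string .
histo:movingObject a owl:ObjectProperty .
histo:movingObject rdfs:domain histo:Relationship .
histo:movingObject rdfs:range histo:PhysicalEntity .
histo:name a owl:DatatypeProperty .
histo:name rdfs:range xsd:string .
histo:parameterName a owl:DatatypeProperty .
histo:parameterName rdfs:domain histo:Quantification .
histo:parameterName rdfs:range xsd:string .
histo:present_Entity a owl:ObjectProperty .
histo:present_Entity rdfs:domain histo:Phenotype .
histo:present_Entity rdfs:range histo:PhysicalEntity .
histo:segmentation a owl:DatatypeProperty .
histo:segmentation rdfs:domain histo:PhysicalEntity .
histo:segmentation rdfs:range xsd:string .
histo:source a owl:DatatypeProperty .
histo:source rdfs:domain histo:Quantification .
histo:source rdfs:range xsd:string .
histo:towards a owl:ObjectProperty .
histo:towards rdfs:domain histo:Relationship .
histo:towards rdfs:range histo:PhysicalEntity .
histo:unit a owl:DatatypeProperty .
histo:unit rdfs:domain histo:Quantification .
histo:unit rdfs:range xsd:string .
histo:value a owl:DatatypeProperty .
histo:value rdfs:domain histo:Quantification .
histo:value rdfs:range xsd:decimal .
histo:width a owl:DatatypeProperty .
histo:width rdfs:domain histo:WholeSlideImage .
histo:width rdfs:range xsd:integer .
histo:xrefId a owl:DatatypeProperty .
histo:xrefId rdfs:domain histo:Xref .
histo:xrefId rdfs:range xsd:string .
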