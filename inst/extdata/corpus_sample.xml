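<?xml version="1.0" encoding="UTF-8"?>
<PubmedArticleSet>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>100001</PMID>
      <Article>
        <ArticleTitle>BRCA1 mutation carriers and breast neoplasms risk.</ArticleTitle>
        <Abstract>
          <AbstractText>We studied BRCA1 in familial breast neoplasms. Carriers showed elevated risk of lung neoplasms.</AbstractText>
        </Abstract>
      </Article>
      <MeshHeadingList>
        <MeshHeading><DescriptorName>Breast Neoplasms</DescriptorName></MeshHeading>
        <MeshHeading><DescriptorName>Humans</DescriptorName></MeshHeading>
        <MeshHeading><DescriptorName>Mutation</DescriptorName></MeshHeading>
      </MeshHeadingList>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>100002</PMID>
      <Article>
        <ArticleTitle>Doxorubicin response in lung neoplasms.</ArticleTitle>
        <Abstract>
          <AbstractText>Doxorubicin improved outcomes. E. coli contamination was excluded.</AbstractText>
        </Abstract>
      </Article>
      <MeshHeadingList>
        <MeshHeading><DescriptorName>Lung Neoplasms</DescriptorName></MeshHeading>
        <MeshHeading><DescriptorName>Doxorubicin</DescriptorName></MeshHeading>
      </MeshHeadingList>
    </MedlineCitation>
  </PubmedArticle>
  <PubmedArticle>
    <MedlineCitation>
      <PMID>100003</PMID>
      <Article>
        <ArticleTitle>Sickle cell anemia and HBB variants.</ArticleTitle>
      </Article>
      <MeshHeadingList>
        <MeshHeading><DescriptorName>Anemia, Sickle Cell</DescriptorName></MeshHeading>
      </MeshHeadingList>
    </MedlineCitation>
  </PubmedArticle>
</PubmedArticleSet>
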