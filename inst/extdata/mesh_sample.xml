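<?xml version="1.0" encoding="UTF-8"?>
<DescriptorRecordSet LanguageCode="eng">
  <DescriptorRecord>
    <DescriptorName><String>Neoplasms</String></DescriptorName>
    <TreeNumberList><TreeNumber>C04</TreeNumber></TreeNumberList>
  </DescriptorRecord>
  <DescriptorRecord>
    <DescriptorName><String>Lung Neoplasms</String></DescriptorName>
    <TreeNumberList>
      <TreeNumber>C04.588.894.797.520</TreeNumber>
      <TreeNumber>C08.381.540</TreeNumber>
    </TreeNumberList>
  </DescriptorRecord>
  <DescriptorRecord>
    <DescriptorName><String>Lung</String></DescriptorName>
    <TreeNumberList><TreeNumber>A04.411</TreeNumber></TreeNumberList>
  </DescriptorRecord>
  <DescriptorRecord>
    <DescriptorName><String>Family</String></DescriptorName>
    <TreeNumberList><TreeNumber>F01.829.263</TreeNumber></TreeNumberList>
  </DescriptorRecord>
  <DescriptorRecord>
    <DescriptorName><String>Humans</String></DescriptorName>
    <TreeNumberList><TreeNumber>B01.050.150.900.649.313.988.400.112.400.400</TreeNumber></TreeNumberList>
  </DescriptorRecord>
  <DescriptorRecord>
    <DescriptorName><String>Doxorubicin</String></DescriptorName>
    <TreeNumberList><TreeNumber>D04.615.562.900.248</TreeNumber></TreeNumberList>
  </DescriptorRecord>
  <DescriptorRecord>
    <DescriptorName><String>Breast Neoplasms</String></DescriptorName>
    <TreeNumberList><TreeNumber>C04.588.180</TreeNumber></TreeNumberList>
  </DescriptorRecord>
  <DescriptorRecord>
    <DescriptorName><String>Mutation</String></DescriptorName>
    <TreeNumberList><TreeNumber>G05.365.590</TreeNumber></TreeNumberList>
  </DescriptorRecord>
  <DescriptorRecord>
    <DescriptorName><String>Anemia, Sickle Cell</String></DescriptorName>
    <TreeNumberList>
      <TreeNumber>C15.378.071.141.150.150</TreeNumber>
    </TreeNumberList>
  </DescriptorRecord>
  <DescriptorRecord>
    <DescriptorName><String>Genetic Markers</String></DescriptorName>
    <TreeNumberList><TreeNumber>G05.360.340.024.340.535</TreeNumber></TreeNumberList>
  </DescriptorRecord>
</DescriptorRecordSet>
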